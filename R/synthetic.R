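# Seeded generator for pen-level feedlot trials with the structure of the
# source experiment: four production-profile classes (PP1, PP2+, PP2-, PP3),
# three diets, and per PP class three solitary pens plus six four-animal pens
# (27 animals), allocated to pens by weight-ranked blocking and randomised to
# diets within rank blocks. Trait distributions default to the published
# cohort means with SDs recovered from their 95% CIs.

#' Default trait generators derived from the built-in study cohorts
#'
#' Entry live weight is a property of the animal before diet allocation, so
#' it is generated per PP class (n-weighted mean and pooled SD across that
#' class's diet cells). Carcass gain and daily intake are generated per
#' (PP, diet) cell. The PP2+ and PP2- subclasses inherit the pooled PP2
#' parameters with the gain mean shifted by `+/- gain_offset` (the published
#' tables report only the pooled class).
#'
#' @param gain_offset Relative gain-mean shift for PP2+ / PP2- (default 0.03).
#' @return A list with elements `entry` (tibble `pp`, `mean`, `sd`) and
#'   `cell` (tibble `pp`, `diet`, `gain_mean`, `gain_sd`, `dmi_mean`,
#'   `dmi_sd`).
#' @export
default_trait_generators <- function(gain_offset = 0.03) {
  t1 <- builtin_table1()
  t1$entry_sd <- sd_from_ci(t1$entry_wt_lo, t1$entry_wt_hi, t1$n)
  t1$gain_sd <- sd_from_ci(t1$gain_lo, t1$gain_hi, t1$n)
  t1$dmi_sd <- sd_from_ci(t1$dmi_lo, t1$dmi_hi, t1$n)
  entry <- t1 %>%
    group_by(.data$pp) %>%
    summarise(
      mean = sum(.data$n * .data$entry_wt_mean) / sum(.data$n),
      sd = sqrt(sum((.data$n - 1) * .data$entry_sd^2 +
                      .data$n * (.data$entry_wt_mean -
                                   sum(.data$n * .data$entry_wt_mean) / sum(.data$n))^2) /
                  (sum(.data$n) - 1)),
      .groups = "drop")
  cell <- t1 %>%
    select("pp", "diet", gain_mean = "gain_mean", gain_sd = "gain_sd",
           dmi_mean = "dmi_mean", dmi_sd = "dmi_sd")
  split2 <- function(tb, label, shift) {
    out <- tb %>% filter(.data$pp == "PP2")
    out$pp <- label
    out$gain_mean <- out$gain_mean * (1 + shift)
    out
  }
  entry2 <- entry %>% filter(.data$pp == "PP2")
  entry <- bind_rows(entry,
                     mutate(entry2, pp = "PP2+"),
                     mutate(entry2, pp = "PP2-"))
  cell <- bind_rows(cell,
                    split2(cell, "PP2+", gain_offset),
                    split2(cell, "PP2-", -gain_offset))
  list(entry = entry, cell = cell)
}

#' Design of a synthetic feedlot trial
#'
#' @param pp_classes PP classes to generate (default the four raw classes).
#' @param diets Diet names (default LPD, MPD, HPD).
#' @param pen_sizes Pen sizes per PP class; the default — three solitary pens
#'   and six pens of four — gives 27 animals per class in 9 pens, 3 pens
#'   (one solitary, two of four) per diet. Each pen size must occur a
#'   multiple of `length(diets)` times so every diet receives the same pen
#'   structure; otherwise the partition is impossible and an error is raised.
#' @param days_on_feed Feeding period, days.
#' @param trait_generators Trait distribution table as returned by
#'   [default_trait_generators()].
#' @param intake_gain_cor Correlation between the gain and intake draws of an
#'   animal (default 0.5; set 0 for independence, matching the assumption of
#'   the Monte-Carlo module).
#' @param dropout Per-animal probability of exclusion from the final records
#'   (default 0).
#' @param seed Integer seed; the whole trial is deterministic given the design.
#' @return A list of class `fl_trial_design`.
#' @export
trial_design <- function(pp_classes = c("PP1", "PP2+", "PP2-", "PP3"),
                         diets = diet_levels(),
                         pen_sizes = c(1, 1, 1, 4, 4, 4, 4, 4, 4),
                         days_on_feed = 142,
                         trait_generators = default_trait_generators(),
                         intake_gain_cor = 0.5,
                         dropout = 0,
                         seed = 1) {
  if (!all(pp_classes %in% pp_levels()))
    abort("unknown pp class in design", class = "fl_validation_error")
  if (!all(diets %in% diet_levels()))
    abort("unknown diet in design", class = "fl_validation_error")
  size_counts <- table(pen_sizes)
  if (length(pen_sizes) == 0 || any(pen_sizes < 1) ||
      any(size_counts %% length(diets) != 0))
    abort("impossible pen partition: each pen size must occur a multiple of length(diets) times",
          class = "fl_validation_error")
  if (abs(intake_gain_cor) > 1)
    abort("intake_gain_cor must lie in [-1, 1]", class = "fl_validation_error")
  if (dropout < 0 || dropout >= 1)
    abort("dropout must lie in [0, 1)", class = "fl_validation_error")
  structure(list(
    pp_classes = pp_classes, diets = diets,
    pen_sizes = as.integer(pen_sizes),
    n_per_cell = sum(pen_sizes) / length(diets),
    days_on_feed = days_on_feed,
    trait_generators = trait_generators,
    intake_gain_cor = intake_gain_cor,
    dropout = dropout,
    seed = as.integer(seed)
  ), class = "fl_trial_design")
}

#' @export
print.fl_trial_design <- function(x, ...) {
  cat("<fl_trial_design>\n")
  cat("  PP classes:", paste(x$pp_classes, collapse = ", "), "\n")
  cat("  diets:     ", paste(x$diets, collapse = ", "), "\n")
  cat(sprintf("  pens/PP:    %s (%d animals per PP, %g per cell)\n",
              paste(x$pen_sizes, collapse = "+"), sum(x$pen_sizes), x$n_per_cell))
  cat(sprintf("  DOF %d, intake-gain cor %.2f, dropout %.2f, seed %d\n",
              as.integer(x$days_on_feed), x$intake_gain_cor, x$dropout, x$seed))
  invisible(x)
}

# positive-truncated normal draw by per-element redraw
draw_pos <- function(n, mean, sd, lower = 0) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a synthetic feedlot trial
#'
#' Per PP class: draws entry live weights, ranks the animals by weight,
#' splits the ranking into blocks of `length(diets)` and randomises the
#' diets within each block (the pen allocation of the source design), then
#' draws carcass gain and daily intake from the animal's (PP, diet) cell
#' distributions with the design's intake-gain correlation. Entry carcass
#' weight uses the live-to-carcass conversion, and exit carcass weight is
#' entry carcass weight plus the gain draw, so the generated records are
#' internally consistent on a carcass basis. Draws implying a non-positive
#' gain, intake or carcass weight are rejected and redrawn.
#'
#' @param design A [trial_design()].
#' @return A tibble of animal records: `animal_id`, `pp`, `diet`, `pen_id`,
#'   `entry_weight` (kg live), `exit_carcass_weight` (kg), `total_intake`
#'   (kg feed), `days_on_feed`.
#' @examples
#' generate_trial(trial_design(seed = 7))
#' @export
generate_trial <- function(design) {
  stopifnot(inherits(design, "fl_trial_design"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(design$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  gens <- design$trait_generators
  conv <- carcass_conversion()
  min_entry <- -conv$intercept / conv$slope  # entry must give a positive carcass
  n_diets <- length(design$diets)
  dof <- design$days_on_feed
  rho <- design$intake_gain_cor
  records <- purrr::map(design$pp_classes, function(pp) {
    epar <- gens$entry %>% filter(.data$pp == !!pp)
    if (nrow(epar) != 1)
      abort(paste0("no entry-weight generator for ", pp), class = "fl_validation_error")
    n_animals <- sum(design$pen_sizes)
    entry <- draw_pos(n_animals, epar$mean, epar$sd, lower = min_entry)
    ord <- order(entry, decreasing = TRUE)
    entry <- entry[ord]
    # weight-ranked blocks of one animal per diet, diets randomised in-block
    diet_of <- unlist(lapply(seq_len(n_animals / n_diets), function(b)
      sample(design$diets)))
    # every diet receives the same pen-size multiset; pens filled in ranking
    # order so pen mates are weight neighbours
    tab <- table(design$pen_sizes) / n_diets
    per_diet_sizes <- sort(rep(as.integer(names(tab)), times = tab),
                           decreasing = TRUE)
    pens <- stats::setNames(rep(list(per_diet_sizes), n_diets), design$diets)
    pen_id <- character(n_animals)
    for (d in design$diets) {
      idx <- which(diet_of == d)
      sizes <- pens[[d]]
      lab <- rep(paste0(pp, "_", d, "_pen", seq_along(sizes)), times = sizes)
      pen_id[idx] <- lab
    }
    # correlated (gain, intake) draws per animal from its cell distribution
    gain <- numeric(n_animals); dmi <- numeric(n_animals)
    for (d in design$diets) {
      idx <- which(diet_of == d)
      cpar <- gens$cell %>% filter(.data$pp == !!pp, .data$diet == d)
      if (nrow(cpar) != 1)
        abort(paste0("no cell generator for (", pp, ", ", d, ")"),
              class = "fl_validation_error")
      k <- length(idx)
      repeat {
        z1 <- rnorm(k); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(k)
        g <- cpar$gain_mean + cpar$gain_sd * z1
        i <- cpar$dmi_mean + cpar$dmi_sd * z2
        bad <- g <= 0 | i <= 0
        if (!any(bad)) { gain[idx] <- g; dmi[idx] <- i; break }
        ok <- !bad
        gain[idx[ok]] <- g[ok]; dmi[idx[ok]] <- i[ok]
        idx <- idx[bad]; k <- length(idx)
      }
    }
    tibble(
      pp = pp, diet = diet_of, pen_id = pen_id,
      entry_weight = entry,
      exit_carcass_weight = entry_carcass_weight(entry, conv) + gain,
      total_intake = dmi * dof,
      days_on_feed = dof
    )
  }) %>% bind_rows()
  if (design$dropout > 0) {
    keep <- stats::runif(nrow(records)) >= design$dropout
    records <- records[keep, , drop = FALSE]
  }
  records %>%
    mutate(animal_id = sprintf("A%03d", row_number())) %>%
    select("animal_id", "pp", "diet", "pen_id", "entry_weight",
           "exit_carcass_weight", "total_intake", "days_on_feed")
}

#' Summarise animal records to cohort production rows
#'
#' Aggregates synthetic (or real) animal records into the cohort schema of
#' [read_cohorts()]: per (PP, diet) cell, trait means with 95% t-intervals.
#' Per-animal carcass gain is exit carcass weight minus the entry carcass
#' weight implied by the live-to-carcass conversion. The carcass feed
#' conversion ratio and daily gain are computed per pen and then averaged
#' (`mean_of_ratios`, the default — what a feedlot recording per-pen feed
#' bunks actually measures) or from cell totals (`ratio_of_means`); the two
#' differ whenever per-pen gains vary (Jensen's inequality, the ratio being
#' convex in its denominator).
#'
#' Cells with a single animal have no within-cell variance; their intervals
#' are reported zero-width and the affected cells are listed in the
#' `ci_undefined` attribute of the result.
#'
#' @param records Animal records as from [generate_trial()].
#' @param aggregation `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @param conv A [carcass_conversion()] for the entry carcass weight.
#' @return A validated cohort tibble, one row per (pp, diet) cell.
#' @export
summarize_to_cohorts <- function(records,
                                 aggregation = c("mean_of_ratios", "ratio_of_means"),
                                 conv = carcass_conversion()) {
  aggregation <- match.arg(aggregation)
  if (nrow(records) == 0)
    abort("no records to summarise", class = "fl_validation_error")
  if (any(tapply(records$days_on_feed,
                 paste(records$pp, records$diet),
                 function(x) length(unique(x))) != 1))
    abort("inconsistent days_on_feed within a cell", class = "fl_validation_error")
  recs <- records %>%
    mutate(
      entry_cw = entry_carcass_weight(.data$entry_weight, conv),
      gain = .data$exit_carcass_weight - .data$entry_cw,
      dmi = .data$total_intake / .data$days_on_feed
    )
  if (any(recs$gain <= 0))
    abort("record with non-positive carcass gain", class = "fl_validation_error")
  mean_ci <- function(x, n) {
    if (n < 2) return(c(mean(x), mean(x), mean(x)))
    half <- qt(0.975, n - 1) * sd(x) / sqrt(n)
    c(mean(x), mean(x) - half, mean(x) + half)
  }
  cells <- recs %>% group_by(.data$pp, .data$diet)
  keys <- dplyr::group_keys(cells)
  groups <- dplyr::group_split(cells)
  undef <- character(0)
  rows <- purrr::map2(groups, seq_along(groups), function(g, i) {
    n <- nrow(g)
    dof <- g$days_on_feed[1]
    pen <- g %>% group_by(.data$pen_id) %>%
      summarise(gain = sum(.data$gain), intake = sum(.data$total_intake),
                k = dplyr::n(), .groups = "drop") %>%
      mutate(cfcr = .data$intake / .data$gain,
             cadg = .data$gain / (.data$k * dof))
    if (aggregation == "mean_of_ratios") {
      cfcr_stats <- mean_ci(pen$cfcr, nrow(pen))
      cadg_stats <- mean_ci(pen$cadg, nrow(pen))
    } else {
      half_f <- if (nrow(pen) >= 2) qt(0.975, nrow(pen) - 1) * sd(pen$cfcr) / sqrt(nrow(pen)) else 0
      half_a <- if (nrow(pen) >= 2) qt(0.975, nrow(pen) - 1) * sd(pen$cadg) / sqrt(nrow(pen)) else 0
      m_f <- sum(pen$intake) / sum(pen$gain)
      m_a <- sum(pen$gain) / (n * dof)
      cfcr_stats <- c(m_f, m_f - half_f, m_f + half_f)
      cadg_stats <- c(m_a, m_a - half_a, m_a + half_a)
    }
    if (n < 2 || nrow(pen) < 2)
      undef <<- c(undef, paste(keys$pp[i], keys$diet[i]))
    ew <- mean_ci(g$entry_weight, n)
    cw <- mean_ci(g$exit_carcass_weight, n)
    gn <- mean_ci(g$gain, n)
    dm <- mean_ci(g$dmi, n)
    dcost <- diet_specs()$cost_per_kg[match(keys$diet[i], diet_specs()$diet)]
    tibble(
      pp = keys$pp[i], diet = keys$diet[i], n = n,
      entry_wt_mean = ew[1], entry_wt_lo = ew[2], entry_wt_hi = ew[3],
      carc_wt_mean = cw[1], carc_wt_lo = cw[2], carc_wt_hi = cw[3],
      cadg_mean = cadg_stats[1], cadg_lo = cadg_stats[2], cadg_hi = cadg_stats[3],
      cfcr_mean = cfcr_stats[1], cfcr_lo = cfcr_stats[2], cfcr_hi = cfcr_stats[3],
      dmi_mean = dm[1], dmi_lo = dm[2], dmi_hi = dm[3],
      gain_mean = gn[1], gain_lo = gn[2], gain_hi = gn[3],
      dof = dof, diet_cost = dcost
    )
  })
  out <- bind_rows(rows)
  # ratio-of-means can sit off-centre of the pen-based interval; widen to keep
  # the interval honest around the reported mean
  for (stem in c("cadg", "cfcr")) {
    m <- out[[paste0(stem, "_mean")]]
    out[[paste0(stem, "_lo")]] <- pmin(out[[paste0(stem, "_lo")]], m)
    out[[paste0(stem, "_hi")]] <- pmax(out[[paste0(stem, "_hi")]], m)
  }
  out <- validate_cohorts(out)
  attr(out, "ci_undefined") <- undef
  out
}

#' Pool the PP2 subclasses of a summarised trial
#'
#' Applies [pool_pp2()] per diet to a cohort table containing `PP2+` and
#' `PP2-` rows, returning the table with the two subclasses replaced by the
#' pooled `PP2` class.
#'
#' @param cohorts A cohort table with PP2+ and PP2- rows.
#' @return A cohort tibble with pooled PP2 rows.
#' @export
pool_pp2_cells <- function(cohorts) {
  cohorts <- validate_cohorts(cohorts)
  plus <- cohorts %>% filter(.data$pp == "PP2+")
  minus <- cohorts %>% filter(.data$pp == "PP2-")
  rest <- cohorts %>% filter(!.data$pp %in% c("PP2+", "PP2-"))
  pooled <- purrr::map(sort(unique(plus$diet)), function(d) {
    p <- plus %>% filter(.data$diet == d)
    m <- minus %>% filter(.data$diet == d)
    if (nrow(p) != 1 || nrow(m) != 1)
      abort(paste0("diet ", d, " lacks a PP2+ / PP2- pair"),
            class = "fl_validation_error")
    pool_pp2(p, m)
  }) %>% bind_rows()
  validate_cohorts(bind_rows(rest, pooled))
}

#' Write animal records to CSV
#'
#' @param records Animal records as from [generate_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_animal_records <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read animal records from CSV
#'
#' @param path Path written by [write_animal_records()].
#' @return A tibble of animal records.
#' @export
read_animal_records <- function(path) {
  if (!file.exists(path)) abort(paste0("records file not found: ", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
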