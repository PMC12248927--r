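# Cohort-level production data: one row per production-profile (PP) class x
# diet cell, holding trait means with 95% confidence intervals. The pooled
# average class is labelled "PP2"; its constituents "PP2+" and "PP2-" appear
# only in raw (unpooled) data.

pp_levels <- function() c("PP1", "PP2+", "PP2-", "PP2", "PP3")
diet_levels <- function() c("LPD", "MPD", "HPD")

cohort_cols <- function() {
  c("pp", "diet", "n",
    "entry_wt_mean", "entry_wt_lo", "entry_wt_hi",
    "carc_wt_mean", "carc_wt_lo", "carc_wt_hi",
    "cadg_mean", "cadg_lo", "cadg_hi",
    "cfcr_mean", "cfcr_lo", "cfcr_hi",
    "dmi_mean", "dmi_lo", "dmi_hi",
    "gain_mean", "gain_lo", "gain_hi",
    "dof", "diet_cost")
}

trait_stems <- function() c("entry_wt", "carc_wt", "cadg", "cfcr", "dmi", "gain")

#' Diet specifications used in the built-in study data
#'
#' The three finishing diets: a low-production diet (LPD, 13% crude protein,
#' 10.6 MJ/kg metabolizable energy), the South African feedlot norm (MPD, 14%,
#' 11.3 MJ/kg), and a high-production diet (HPD, 15%, 12.0 MJ/kg), with their
#' as-fed costs in ZAR per kg.
#'
#' @return A tibble with columns `diet`, `crude_protein`, `metabolizable_energy`,
#'   `cost_per_kg`.
#' @export
diet_specs <- function() {
  tibble(
    diet = diet_levels(),
    crude_protein = c(13, 14, 15),
    metabolizable_energy = c(10.6, 11.3, 12.0),
    cost_per_kg = c(4.73, 5.10, 6.10)
  )
}

#' Validate a cohort table
#'
#' Checks the column set and the row-wise invariants of cohort production
#' data: positive sample sizes and trait means, ordered confidence limits
#' (`lo <= mean <= hi`), carcass gain below carcass exit weight, and known
#' PP/diet labels.
#'
#' @param cohorts A data frame of cohorts (see [read_cohorts()] for the schema).
#' @return The validated table, invisibly coerced to a tibble.
#' @export
validate_cohorts <- function(cohorts) {
  cohorts <- as_tibble(cohorts)
  missing_cols <- setdiff(cohort_cols(), names(cohorts))
  if (length(missing_cols) > 0)
    abort(paste0("cohort table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fl_schema_error")
  if (nrow(cohorts) == 0) return(cohorts[cohort_cols()])
  bad_pp <- !cohorts$pp %in% pp_levels()
  if (any(bad_pp))
    abort(paste0("unknown pp label in row(s) ", paste(which(bad_pp), collapse = ", ")),
          class = "fl_validation_error")
  bad_diet <- !cohorts$diet %in% diet_levels()
  if (any(bad_diet))
    abort(paste0("unknown diet label in row(s) ", paste(which(bad_diet), collapse = ", ")),
          class = "fl_validation_error")
  if (any(cohorts$n < 1))
    abort(paste0("n must be >= 1 (row ", which(cohorts$n < 1)[1], ")"),
          class = "fl_validation_error")
  for (stem in trait_stems()) {
    m <- cohorts[[paste0(stem, "_mean")]]
    lo <- cohorts[[paste0(stem, "_lo")]]
    hi <- cohorts[[paste0(stem, "_hi")]]
    if (any(m <= 0))
      abort(paste0("non-positive mean for trait `", stem, "` in row ",
                   which(m <= 0)[1]),
            class = "fl_validation_error")
    bad <- lo > m | m > hi
    if (any(bad))
      abort(paste0("confidence limits violate lo <= mean <= hi for trait `",
                   stem, "` in row ", which(bad)[1]),
            class = "fl_validation_error")
  }
  if (any(cohorts$gain_mean >= cohorts$carc_wt_mean))
    abort("carcass gain must be below carcass exit weight",
          class = "fl_validation_error")
  if (any(cohorts$dof <= 0) || any(cohorts$diet_cost <= 0))
    abort("dof and diet_cost must be positive", class = "fl_validation_error")
  cohorts[cohort_cols()]
}

#' Read cohort production data from CSV
#'
#' The file is comma-separated UTF-8 with one row per PP x diet cohort and the
#' columns `pp, diet, n, <trait>_mean, <trait>_lo, <trait>_hi` for traits
#' `entry_wt` (kg live), `carc_wt` (kg carcass), `cadg` (kg/d), `cfcr`
#' (kg feed/kg carcass), `dmi` (kg/d), `gain` (kg carcass), then `dof` (days)
#' and `diet_cost` (ZAR/kg feed). Confidence limits are the printed 95%
#' interval bounds.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated cohorts; zero rows if the file has only a
#'   header.
#' @export
read_cohorts <- function(path) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohorts(raw)
}

#' Write cohort production data to CSV
#'
#' Inverse of [read_cohorts()]: the written file re-reads to a field-identical
#' table.
#'
#' @param cohorts A validated cohort table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohorts <- function(cohorts, path) {
  cohorts <- validate_cohorts(cohorts)
  readr::write_csv(cohorts, path, progress = FALSE)
  invisible(path)
}

#' Built-in study cohorts
#'
#' The nine PP x diet cohorts of the source feeding trial: three production
#' profiles (PP1 above-average, PP2 average — the pooled PP2+/PP2- class — and
#' PP3 below-average growth potential) finished for 142 days on each of three
#' diets. Trait means and 95% confidence intervals are carried exactly as
#' recorded; carcass gain is the observed carcass-basis gain over the feeding
#' period.
#'
#' @return A tibble with 9 rows in the [read_cohorts()] schema.
#' @examples
#' builtin_table1()
#' @export
builtin_table1 <- function() {
  tr <- function(m, lo, hi) c(m, lo, hi)
  row <- function(pp, diet, n, entry, carc, cadg, cfcr, dmi, gain, cost) {
    tibble(
      pp = pp, diet = diet, n = n,
      entry_wt_mean = entry[1], entry_wt_lo = entry[2], entry_wt_hi = entry[3],
      carc_wt_mean = carc[1], carc_wt_lo = carc[2], carc_wt_hi = carc[3],
      cadg_mean = cadg[1], cadg_lo = cadg[2], cadg_hi = cadg[3],
      cfcr_mean = cfcr[1], cfcr_lo = cfcr[2], cfcr_hi = cfcr[3],
      dmi_mean = dmi[1], dmi_lo = dmi[2], dmi_hi = dmi[3],
      gain_mean = gain[1], gain_lo = gain[2], gain_hi = gain[3],
      dof = 142, diet_cost = cost
    )
  }
  out <- bind_rows(
    row("PP3", "LPD", 9,  tr(199.2, 186.1, 212.3), tr(231.1, 220.7, 241.5),
        tr(0.84, 0.79, 0.90), tr(10.62, 9.69, 11.55), tr(8.69, 7.09, 10.28),
        tr(119.5, 111.5, 127.5), 4.73),
    row("PP2", "LPD", 17, tr(212.7, 204.1, 221.3), tr(269.2, 255.1, 283.4),
        tr(1.04, 0.96, 1.13), tr(10.29, 9.67, 10.90), tr(10.74, 9.64, 11.85),
        tr(148.3, 136.8, 159.8), 4.73),
    row("PP1", "LPD", 8,  tr(224.6, 212.6, 236.7), tr(285.8, 267.6, 304.0),
        tr(1.10, 1.01, 1.20), tr(9.82, 9.75, 9.89), tr(11.19, 10.03, 12.36),
        tr(156.6, 143.3, 169.8), 4.73),
    row("PP3", "MPD", 9,  tr(200.0, 181.4, 218.6), tr(252.6, 232.7, 272.5),
        tr(1.00, 0.92, 1.06), tr(9.81, 9.20, 10.42), tr(9.70, 9.51, 9.89),
        tr(140.5, 130.6, 150.3), 5.10),
    row("PP2", "MPD", 16, tr(211.7, 200.2, 223.2), tr(285.2, 270.0, 300.5),
        tr(1.16, 1.08, 1.24), tr(9.04, 8.63, 9.45), tr(10.28, 9.71, 10.85),
        tr(165.0, 153.3, 176.7), 5.10),
    row("PP1", "MPD", 9,  tr(229.4, 213.3, 245.6), tr(301.1, 286.8, 315.3),
        tr(1.19, 1.10, 1.27), tr(9.18, 8.36, 10.00), tr(11.03, 10.35, 11.71),
        tr(168.5, 156.7, 180.3), 5.10),
    row("PP3", "HPD", 9,  tr(205.1, 187.4, 222.8), tr(258.7, 241.2, 276.2),
        tr(1.01, 0.91, 1.10), tr(9.40, 7.34, 11.49), tr(8.81, 8.48, 9.14),
        tr(143.0, 129.1, 156.9), 6.10),
    row("PP2", "HPD", 18, tr(215.8, 207.4, 224.3), tr(294.0, 280.0, 306.0),
        tr(1.20, 1.13, 1.28), tr(8.59, 8.17, 9.01), tr(10.35, 9.65, 11.05),
        tr(170.8, 160.4, 181.3), 6.10),
    row("PP1", "HPD", 9,  tr(225.4, 212.0, 239.0), tr(319.1, 305.1, 333.1),
        tr(1.33, 1.27, 1.40), tr(8.03, 7.53, 8.54), tr(10.69, 9.95, 11.43),
        tr(189.3, 179.8, 198.8), 6.10)
  )
  validate_cohorts(out)
}

#' Pool the two average-potential subclasses into one cohort
#'
#' Combines a PP2+ and a PP2- cohort on the same diet into the pooled PP2
#' class. Trait means are n-weighted averages; the pooled 95% confidence
#' interval is rebuilt from the pooled standard deviation
#' \deqn{s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2 + n_1(m_1-m)^2 + n_2(m_2-m)^2}{n_1+n_2-1}}
#' which is exact for pooling raw samples with those moments (the subclass
#' SDs are recovered from their t-based confidence intervals).
#'
#' @param plus,minus One-row cohort tables for the PP2+ and PP2- subclasses,
#'   sharing diet and days on feed.
#' @return A one-row cohort tibble labelled `PP2` with `n = n_plus + n_minus`.
#' @export
pool_pp2 <- function(plus, minus) {
  plus <- validate_cohorts(plus)
  minus <- validate_cohorts(minus)
  if (nrow(plus) != 1 || nrow(minus) != 1)
    abort("pool_pp2 expects one-row cohort tables", class = "fl_validation_error")
  if (plus$diet != minus$diet)
    abort("cannot pool cohorts on different diets", class = "fl_validation_error")
  if (plus$dof != minus$dof)
    abort("cannot pool cohorts with different days on feed",
          class = "fl_validation_error")
  n1 <- plus$n; n2 <- minus$n; np <- n1 + n2
  out <- plus
  out$pp <- "PP2"
  out$n <- np
  for (stem in trait_stems()) {
    m1 <- plus[[paste0(stem, "_mean")]]
    m2 <- minus[[paste0(stem, "_mean")]]
    s1 <- sd_from_ci(plus[[paste0(stem, "_lo")]], plus[[paste0(stem, "_hi")]], n1)
    s2 <- sd_from_ci(minus[[paste0(stem, "_lo")]], minus[[paste0(stem, "_hi")]], n2)
    m <- (n1 * m1 + n2 * m2) / np
    sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2 +
                  n1 * (m1 - m)^2 + n2 * (m2 - m)^2) / (np - 1))
    half <- qt(0.975, np - 1) * sp / sqrt(np)
    out[[paste0(stem, "_mean")]] <- m
    out[[paste0(stem, "_lo")]] <- m - half
    out[[paste0(stem, "_hi")]] <- m + half
  }
  validate_cohorts(out)
}

#' Published cost ledger of the built-in study cohorts
#'
#' The A-G economics the source trial published for the nine cohorts, carried
#' as printed: purchase cost (A), feeding cost at the feeding-line rate (B),
#' total carcass cost (C), carcass income (D), carcass feed cost of gain (E),
#' profit (F) and margin in percent (G). Used as the validation reference for
#' the model; see [evaluate_grid()] for the computed counterpart. The printed
#' income for PP1 on HPD (17,550.00) is inconsistent with its own profit row,
#' which implies 17,550.50 (= 319.1 kg x 55 ZAR/kg); the value carried here
#' is the printed one.
#'
#' @return A tibble with columns `pp`, `diet`, `A`, `B`, `C`, `D`, `E`, `F`,
#'   `G`, one row per cohort in [builtin_table1()] order.
#' @export
builtin_table2 <- function() {
  tibble(
    pp   = c("PP3", "PP2", "PP1", "PP3", "PP2", "PP1", "PP3", "PP2", "PP1"),
    diet = c("LPD", "LPD", "LPD", "MPD", "MPD", "MPD", "HPD", "HPD", "HPD"),
    A = c(6926.17, 7395.57, 7809.33, 6953.99, 7360.80, 7976.22,
          7131.31, 7503.35, 7837.14),
    B = c(5951.52, 7355.50, 7663.69, 7152.96, 7580.66, 8133.73,
          7772.01, 9130.75, 9430.51),
    C = c(12897.56, 14775.63, 15498.61, 14130.83, 14966.77, 16137.11,
          14929.28, 16664.41, 17299.15),
    D = c(12710.50, 14806.00, 15719.00, 13893.00, 15686.00, 16560.50,
          14228.50, 16170.00, 17550.00),
    E = c(49.80, 49.60, 48.94, 50.91, 45.94, 48.27, 54.35, 53.46, 49.82),
    F = c(-187.06, 30.37, 220.39, -237.83, 719.23, 423.39,
          -700.78, -494.41, 251.35),
    G = c(-1.45, 0.21, 1.42, -1.68, 4.81, 2.62, -4.69, -2.97, 1.45)
  )
}
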