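# Grid evaluation over PP x diet cells and the comparative statements a
# feedlot manager would read off it: which diet suits each production
# profile, and by how much a candidate diet improves the margin over the
# feedlot-norm baseline.

#' Evaluate the break-even model over a PP x diet grid
#'
#' Runs the full A-G cost ledger for every cohort row: financed purchase cost
#' (A), feeding cost at the feeding-line rate (B), total carcass cost (C),
#' carcass income (D), carcass feed cost of gain (E = B / gain), profit
#' (F = D - C) and margin (G = 100 F / C), plus both break-even prices.
#'
#' @param cohorts A cohort table with unique (pp, diet) keys.
#' @param params An [econ_params()].
#' @return A tibble of class `fl_scenario`, one row per cohort, carrying the
#'   parameters as an attribute.
#' @examples
#' evaluate_grid(builtin_table1())
#' @export
evaluate_grid <- function(cohorts, params = econ_params()) {
  cohorts <- validate_cohorts(cohorts)
  if (nrow(cohorts) == 0) abort("cohorts must be non-empty", class = "fl_validation_error")
  key <- paste(cohorts$pp, cohorts$diet)
  if (anyDuplicated(key) > 0)
    abort(paste0("duplicate (pp, diet) cell: ", key[anyDuplicated(key)]),
          class = "fl_validation_error")
  out <- eval_cohort_econ(cohorts, params)
  attr(out, "params") <- params
  class(out) <- c("fl_scenario", class(out))
  out
}

grid_metrics <- function() c("profit_F", "margin_G", "cfcog_E")

#' Best diet per production profile
#'
#' For each PP class, the diet that maximises profit or margin, or minimises
#' the carcass feed cost of gain. Ties break toward the cheaper diet, then
#' alphabetically.
#'
#' @param table An `fl_scenario` from [evaluate_grid()].
#' @param metric One of `"profit_F"`, `"margin_G"`, `"cfcog_E"`.
#' @return A tibble with columns `pp`, `diet`, and the metric value.
#' @examples
#' best_diet_per_pp(evaluate_grid(builtin_table1()), "profit_F")
#' @export
best_diet_per_pp <- function(table, metric = "profit_F") {
  if (!metric %in% grid_metrics())
    abort(paste0("unknown metric `", metric, "`; use one of: ",
                 paste(grid_metrics(), collapse = ", ")),
          class = "fl_domain_error")
  costs <- diet_specs()[, c("diet", "cost_per_kg")]
  sign <- if (metric == "cfcog_E") 1 else -1
  as_tibble(table) %>%
    left_join(costs, by = "diet") %>%
    mutate(.score = sign * .data[[metric]]) %>%
    group_by(.data$pp) %>%
    arrange(.data$.score, .data$cost_per_kg, .data$diet, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    arrange(factor(.data$pp, levels = pp_levels())) %>%
    select("pp", "diet", dplyr::all_of(metric))
}

#' Relative margin improvement of one diet over a baseline
#'
#' Compares a candidate diet against a baseline diet for one PP class on the
#' magnitude of the profit margin: `100 * (|G_baseline| - |G_candidate|) /
#' |G_baseline|`. Using magnitudes makes a shrinking loss read as a positive
#' improvement, the natural reading when both cells are loss-making.
#'
#' @param table An `fl_scenario`.
#' @param pp PP class label.
#' @param diet Candidate diet name.
#' @param baseline Baseline diet name.
#' @return Percent improvement (positive = candidate better).
#' @examples
#' relative_margin_change(evaluate_grid(builtin_table1()), "PP3", "LPD", "MPD")
#' @export
relative_margin_change <- function(table, pp, diet, baseline) {
  cell <- function(d) {
    r <- as_tibble(table) %>% filter(.data$pp == !!pp, .data$diet == d)
    if (nrow(r) != 1)
      abort(paste0("no cell for (", pp, ", ", d, ")"), class = "fl_domain_error")
    r$margin_G
  }
  g_a <- cell(diet); g_b <- cell(baseline)
  if (g_b == 0)
    abort("baseline margin is exactly zero; relative change undefined",
          class = "fl_domain_error")
  100 * (abs(g_b) - abs(g_a)) / abs(g_b)
}

table2_rows <- function() {
  tibble(
    row = LETTERS[1:7],
    label = c("A: Purchase cost (ZAR)", "B: Feeding cost (ZAR)",
              "C: Carcass cost per animal (ZAR)",
              "D: Carcass income per animal (ZAR)",
              "E: Carcass feed cost of gain (ZAR/kg carcass)",
              "F: Profit/loss per animal (ZAR)", "G: Profit margin (%)"),
    field = c("purchase_cost_A", "feed_cost_B", "total_cost_C", "income_D",
              "cfcog_E", "profit_F", "margin_G")
  )
}

#' Render the A-G ledger as a diet x PP report
#'
#' Pure presentation over an evaluated grid: rows A through G, one column per
#' (diet, PP) cell, values rounded to 2 decimals with an ASCII minus sign.
#' Row B is the feeding-cost line at the feeding-line interest rate; when
#' that rate differs from the canonical annual rate a footnote says so.
#'
#' @param table An `fl_scenario`.
#' @param format `"tibble"` for a wide tibble of formatted strings, `"text"`
#'   for aligned plain-text lines (footnote included), `"csv"` for CSV lines.
#' @return A tibble or character vector according to `format`.
#' @export
render_table2 <- function(table, format = c("tibble", "text", "csv")) {
  format <- match.arg(format)
  tab <- as_tibble(table)
  params <- attr(table, "params")
  rows <- table2_rows()
  if (nrow(tab) == 0) {
    wide <- rows[, "label"]
  } else {
    tab <- tab %>%
      arrange(factor(.data$diet, levels = diet_levels()),
              factor(.data$pp, levels = pp_levels()))
    cells <- paste(tab$diet, tab$pp, sep = "_")
    wide <- rows[, "label"]
    for (j in seq_along(cells)) {
      vals <- vapply(rows$field, function(f) tab[[f]][j], numeric(1))
      wide[[cells[j]]] <- sprintf("%.2f", vals)
    }
  }
  if (format == "tibble") return(wide)
  if (format == "csv")
    return(strsplit(sub("\n$", "", readr::format_csv(wide)), "\n")[[1]])
  # aligned text
  mat <- as.matrix(wide)
  mat <- rbind(colnames(wide), mat)
  widths <- apply(nchar(mat), 2, max)
  out <- apply(mat, 1, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
  if (!is.null(params) && !is.null(params$feed_interest_rate_override) &&
      params$feed_interest_rate_override != params$annual_interest_rate) {
    out <- c(out, sprintf(
      "Note: row B financed at %.2f%%/yr on %.0f%% of the feed principal; rows C, F, G finance feed at %.2f%%/yr.",
      100 * params$feed_interest_rate_override, 100 * params$feed_financed_fraction,
      100 * params$annual_interest_rate))
  }
  unname(out)
}

#' @export
print.fl_scenario <- function(x, ...) {
  cat("# Break-even grid:", nrow(x), "cohort cell(s)\n")
  NextMethod()
}

#' Tidy an evaluated grid into a long ledger
#'
#' One row per (pp, diet, ledger line), broom-style.
#'
#' @param x An `fl_scenario`.
#' @param ... Unused.
#' @return A tibble with columns `pp`, `diet`, `line`, `value`.
#' @export
tidy.fl_scenario <- function(x, ...) {
  as_tibble(x) %>%
    select("pp", "diet", dplyr::all_of(table2_rows()$field)) %>%
    tidyr::pivot_longer(-c("pp", "diet"), names_to = "line", values_to = "value")
}

#' One-line summary of an evaluated grid
#'
#' @param x An `fl_scenario`.
#' @param ... Unused.
#' @return A one-row tibble: cell count, total and best profit, the best
#'   (pp, diet) cell, and the share of loss-making cells.
#' @export
glance.fl_scenario <- function(x, ...) {
  tab <- as_tibble(x)
  best <- tab[which.max(tab$profit_F), ]
  tibble(
    n_cells = nrow(tab),
    total_profit = sum(tab$profit_F),
    best_profit = best$profit_F,
    best_pp = best$pp,
    best_diet = best$diet,
    frac_loss = mean(tab$profit_F < 0)
  )
}

#' Profit-by-diet plot for an evaluated grid
#'
#' Bar chart of profit per animal across PP classes, facetted by diet.
#'
#' @param object An `fl_scenario`.
#' @param metric Ledger column to plot (default `"profit_F"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fl_scenario <- function(object, metric = "profit_F", ...) {
  tab <- as_tibble(object) %>%
    mutate(pp = factor(.data$pp, levels = pp_levels()),
           diet = factor(.data$diet, levels = diet_levels()))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pp, y = .data[[metric]],
                                    fill = .data$pp)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$diet)) +
    ggplot2::labs(x = "Production profile", y = metric) +
    ggplot2::theme_minimal()
}
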