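# Uncertainty propagation: back-converting the published 95% confidence
# intervals to trait standard deviations, one-at-a-time price/trait
# sensitivity, and a seeded Monte-Carlo engine that pushes trait variation
# through the full-precision cost ledger into a profit distribution.

#' Standard deviation from a 95% confidence interval of the mean
#'
#' Inverts the t-based interval `mean +/- t_{0.975, n-1} * sd / sqrt(n)`:
#' `sd = sqrt(n) * (hi - lo) / (2 * t_{0.975, n-1})`. If the source interval
#' was z-based instead, this overestimates the SD by the factor
#' `t_{0.975, n-1} / 1.96`.
#'
#' @param ci_lo,ci_hi Interval bounds (vectorised); `ci_hi >= ci_lo`.
#' @param n Sample size behind the interval (>= 2).
#' @return Standard deviation in trait units.
#' @examples
#' sd_from_ci(204.1, 221.3, 17)
#' @export
sd_from_ci <- function(ci_lo, ci_hi, n) {
  if (any(n < 2)) abort("n must be >= 2 to invert a CI", class = "fl_domain_error")
  if (any(ci_hi < ci_lo)) abort("ci_hi must be >= ci_lo", class = "fl_domain_error")
  sqrt(n) * (ci_hi - ci_lo) / (2 * qt(0.975, n - 1))
}

#' 95% confidence interval of the mean from a known SD
#'
#' Exact inverse of [sd_from_ci()].
#'
#' @param mean Trait mean.
#' @param sd Standard deviation (>= 0).
#' @param n Sample size (>= 2).
#' @return A tibble with columns `lo`, `hi`.
#' @export
ci_from_sd <- function(mean, sd, n) {
  if (any(n < 2)) abort("n must be >= 2", class = "fl_domain_error")
  half <- qt(0.975, n - 1) * sd / sqrt(n)
  tibble(lo = mean - half, hi = mean + half)
}

oat_params <- function() c("live_price", "carcass_price", "diet_cost",
                           "annual_interest_rate", "daily_intake", "carcass_gain")

#' One-at-a-time sensitivity of profit
#'
#' Re-evaluates the cohort's profit with a single input perturbed to
#' `(1 - delta)` and `(1 + delta)` times its base value, everything else
#' fixed. The elasticity is the central-difference relative response
#' `((F_hi - F_lo) / (2 F_base)) / delta`; when the base profit is zero it is
#' reported as the absolute half-range response instead (flagged by
#' `elasticity_absolute`).
#'
#' @param cohort A one-row cohort table.
#' @param params An [econ_params()].
#' @param param One of `"live_price"`, `"carcass_price"`, `"diet_cost"`,
#'   `"annual_interest_rate"`, `"daily_intake"`, `"carcass_gain"`.
#' @param delta Relative perturbation (>= 0).
#' @return A one-row tibble: `param`, `delta`, `profit_low`, `profit_base`,
#'   `profit_high`, `elasticity`, `elasticity_absolute`.
#' @examples
#' oat_sensitivity(builtin_table1()[5, ], econ_params(), "carcass_price", 0.1)
#' @export
oat_sensitivity <- function(cohort, params = econ_params(), param, delta = 0.1) {
  cohort <- validate_cohorts(cohort)
  if (nrow(cohort) != 1)
    abort("oat_sensitivity expects a single cohort row", class = "fl_validation_error")
  if (!param %in% oat_params())
    abort(paste0("unknown parameter `", param, "`; use one of: ",
                 paste(oat_params(), collapse = ", ")),
          class = "fl_domain_error")
  if (delta < 0) abort("delta must be >= 0", class = "fl_domain_error")
  perturbed <- function(scale) {
    co <- cohort; pa <- params
    switch(param,
      live_price = { pa$live_price <- pa$live_price * scale },
      carcass_price = { pa$carcass_price <- pa$carcass_price * scale },
      annual_interest_rate = {
        pa$annual_interest_rate <- pa$annual_interest_rate * scale
        if (!is.null(pa$feed_interest_rate_override))
          pa$feed_interest_rate_override <- pa$feed_interest_rate_override * scale
      },
      diet_cost = { co$diet_cost <- co$diet_cost * scale },
      daily_intake = { co$dmi_mean <- co$dmi_mean * scale },
      carcass_gain = { co$gain_mean <- co$gain_mean * scale }
    )
    eval_cohort_econ(co, pa)$profit_F
  }
  f_base <- perturbed(1)
  f_lo <- perturbed(1 - delta)
  f_hi <- perturbed(1 + delta)
  if (delta == 0) {
    ela <- NA_real_; abs_flag <- FALSE
  } else if (f_base != 0) {
    ela <- ((f_hi - f_lo) / (2 * f_base)) / delta
    abs_flag <- FALSE
  } else {
    ela <- (f_hi - f_lo) / 2
    abs_flag <- TRUE
  }
  tibble(param = param, delta = delta,
         profit_low = f_lo, profit_base = f_base, profit_high = f_hi,
         elasticity = ela, elasticity_absolute = abs_flag)
}

# Moment-matched draws for one trait. Antithetic pairing uses (z, -z): exact
# for the mean of a linear functional under the normal family.
draw_trait <- function(z, mean, sd, family) {
  if (family == "normal") return(mean + sd * z)
  # lognormal matched to the requested mean and sd
  if (mean <= 0) abort("lognormal family requires a positive mean", class = "fl_domain_error")
  if (sd == 0) return(rep(mean, length(z)))
  s2 <- log(1 + (sd / mean)^2)
  exp(log(mean) - s2 / 2 + sqrt(s2) * z)
}

#' Monte-Carlo profit distribution for one cohort
#'
#' Draws entry live weight, carcass exit weight, daily intake and carcass
#' gain from trait distributions whose SDs come from the cohort's published
#' 95% CIs via [sd_from_ci()] (traits are sampled independently; the study
#' reports no covariances), pushes each draw through the full-precision cost
#' ledger, and summarises the resulting profit distribution.
#'
#' Draws with any non-positive trait (in particular non-positive carcass
#' gain) are rejected and redrawn; the rejection fraction is reported and a
#' flag raised when it exceeds 10%. By default draws are antithetic pairs
#' `(z, -z)`, which preserves the profit mean exactly because profit is
#' linear in every sampled trait; set `antithetic = FALSE` for plain
#' independent sampling.
#'
#' @param cohort A one-row cohort table.
#' @param params An [econ_params()].
#' @param n_draws Number of profit draws (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical summaries.
#' @param family `"normal"` or `"lognormal"` trait distributions.
#' @param antithetic Use antithetic variance reduction (default `TRUE`).
#' @return An object of class `fl_mc`: a list with the draw vector and the
#'   summary fields `n_draws`, `profit_mean`, `profit_sd`, `profit_q2.5`,
#'   `profit_q97.5`, `prob_loss`, `seed`, `rng_kind`, `n_rejected`,
#'   `rejection_fraction`, `rejection_warning`, `deterministic_profit`.
#' @examples
#' monte_carlo(builtin_table1()[5, ], econ_params(), n_draws = 1000, seed = 1)
#' @export
monte_carlo <- function(cohort, params = econ_params(), n_draws = 10000,
                        seed = 1, family = c("normal", "lognormal"),
                        antithetic = TRUE) {
  family <- match.arg(family)
  cohort <- validate_cohorts(cohort)
  if (nrow(cohort) != 1)
    abort("monte_carlo expects a single cohort row", class = "fl_validation_error")
  if (n_draws < 1) abort("n_draws must be >= 1", class = "fl_domain_error")
  n <- cohort$n
  traits <- tibble(
    name = c("entry_wt", "carc_wt", "dmi", "gain"),
    mean = c(cohort$entry_wt_mean, cohort$carc_wt_mean,
             cohort$dmi_mean, cohort$gain_mean),
    sd = c(sd_from_ci(cohort$entry_wt_lo, cohort$entry_wt_hi, n),
           sd_from_ci(cohort$carc_wt_lo, cohort$carc_wt_hi, n),
           sd_from_ci(cohort$dmi_lo, cohort$dmi_hi, n),
           sd_from_ci(cohort$gain_lo, cohort$gain_hi, n))
  )
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  rng_kind <- "Mersenne-Twister/Inversion"

  draw_block <- function(m) {
    # returns an m x 4 matrix of trait draws (m even when antithetic)
    z <- matrix(rnorm(m * 4), ncol = 4)
    if (antithetic) z <- rbind(z, -z)
    vapply(seq_len(4), function(j)
      draw_trait(z[, j], traits$mean[j], traits$sd[j], family),
      numeric(nrow(z)))
  }

  unit <- if (antithetic) 2L else 1L
  need <- as.integer(ceiling(n_draws / unit))
  acc <- NULL
  n_rejected <- 0L
  while (is.null(acc) || nrow(acc) < need * unit) {
    want <- need - if (is.null(acc)) 0L else nrow(acc) %/% unit
    block <- draw_block(want)
    if (antithetic) {
      # reject a pair if either member has a non-positive trait
      m <- nrow(block) / 2
      bad1 <- rowSums(block[seq_len(m), , drop = FALSE] <= 0) > 0
      bad2 <- rowSums(block[m + seq_len(m), , drop = FALSE] <= 0) > 0
      bad_pair <- bad1 | bad2
      n_rejected <- n_rejected + 2L * sum(bad_pair)
      keep <- c(which(!bad_pair), m + which(!bad_pair))
      block <- block[keep, , drop = FALSE]
    } else {
      bad <- rowSums(block <= 0) > 0
      n_rejected <- n_rejected + sum(bad)
      block <- block[!bad, , drop = FALSE]
    }
    acc <- if (is.null(acc)) block else rbind(acc, block)
  }
  acc <- acc[seq_len(need * unit), , drop = FALSE]

  co <- cohort[rep(1, nrow(acc)), ]
  co$entry_wt_mean <- acc[, 1]
  co$carc_wt_mean <- acc[, 2]
  co$dmi_mean <- acc[, 3]
  co$gain_mean <- acc[, 4]
  profit <- eval_cohort_econ(co, params)$profit_F
  rej_frac <- n_rejected / (n_rejected + length(profit))
  out <- list(
    pp = cohort$pp, diet = cohort$diet,
    n_draws = length(profit),
    profit_mean = mean(profit),
    profit_sd = if (length(profit) > 1) sd(profit) else 0,
    profit_q2.5 = unname(quantile(profit, 0.025)),
    profit_q97.5 = unname(quantile(profit, 0.975)),
    prob_loss = mean(profit < 0),
    seed = seed,
    rng_kind = rng_kind,
    family = family,
    antithetic = antithetic,
    n_rejected = n_rejected,
    rejection_fraction = rej_frac,
    rejection_warning = rej_frac > 0.10,
    deterministic_profit = eval_cohort_econ(cohort, params)$profit_F,
    draws = profit
  )
  class(out) <- "fl_mc"
  out
}

#' @export
print.fl_mc <- function(x, ...) {
  cat(sprintf("<fl_mc> %s / %s: %d draws (seed %d, %s%s)\n",
              x$pp, x$diet, x$n_draws, x$seed, x$family,
              if (x$antithetic) ", antithetic" else ""))
  cat(sprintf("  profit mean %.2f ZAR (deterministic %.2f), sd %.2f\n",
              x$profit_mean, x$deterministic_profit, x$profit_sd))
  cat(sprintf("  95%% interval [%.2f, %.2f], P(loss) = %.3f\n",
              x$profit_q2.5, x$profit_q97.5, x$prob_loss))
  if (x$rejection_warning)
    cat(sprintf("  warning: %.1f%% of draws rejected (non-positive trait)\n",
                100 * x$rejection_fraction))
  invisible(x)
}

#' Per-draw tibble of a Monte-Carlo run
#'
#' @param x An `fl_mc` object.
#' @param ... Unused.
#' @return A tibble with columns `draw` and `profit`.
#' @export
tidy.fl_mc <- function(x, ...) {
  tibble(draw = seq_along(x$draws), profit = x$draws)
}

#' One-row summary of a Monte-Carlo run
#'
#' @param x An `fl_mc` object.
#' @param ... Unused.
#' @return A one-row tibble of the summary fields.
#' @export
glance.fl_mc <- function(x, ...) {
  tibble(
    pp = x$pp, diet = x$diet, n_draws = x$n_draws,
    profit_mean = x$profit_mean, profit_sd = x$profit_sd,
    profit_q2.5 = x$profit_q2.5, profit_q97.5 = x$profit_q97.5,
    prob_loss = x$prob_loss,
    deterministic_profit = x$deterministic_profit,
    rejection_fraction = x$rejection_fraction,
    rejection_warning = x$rejection_warning,
    seed = x$seed, rng_kind = x$rng_kind
  )
}

#' Histogram of the simulated profit distribution
#'
#' @param object An `fl_mc` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object with the deterministic profit marked.
#' @export
autoplot.fl_mc <- function(object, bins = 60, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$profit)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = NA) +
    ggplot2::geom_vline(xintercept = object$deterministic_profit,
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Profit per animal (ZAR)", y = "Draws",
                  title = sprintf("%s / %s", object$pp, object$diet)) +
    ggplot2::theme_minimal()
}
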