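# The deterministic A-G economics of one cohort. All money flows are simple
# pro-rata (non-compounded) interest on an ACT/365 (or ACT/360) basis:
# multiplier 1 + fraction * rate * days / basis. Only purchase and feed costs
# are modelled; yard, veterinary and fixed costs are identical across cohorts
# in the source trial and cancel out of every comparison.

#' Simple-interest financing multiplier
#'
#' `1 + financed_fraction * rate * days / basis`: the factor a principal grows
#' by under simple pro-rata interest when only `financed_fraction` of it is
#' financed.
#'
#' @param rate Annual interest rate, fraction/yr (>= 0).
#' @param days Days financed (>= 0).
#' @param basis Day-count basis, days/yr.
#' @param financed_fraction Fraction of the principal financed, in `[0, 1]`.
#' @return Dimensionless multiplier >= 1.
#' @examples
#' financing_multiplier(0.1175, 142, 365, 1)
#' @export
financing_multiplier <- function(rate, days, basis = 365, financed_fraction = 1) {
  if (any(rate < 0) || any(days < 0))
    abort("rate and days must be non-negative", class = "fl_domain_error")
  if (any(basis <= 0)) abort("basis must be positive", class = "fl_domain_error")
  if (any(financed_fraction < 0) || any(financed_fraction > 1))
    abort("financed_fraction must lie in [0, 1]", class = "fl_domain_error")
  1 + financed_fraction * rate * days / basis
}

#' Financed purchase cost of the feeder calf (ledger line A)
#'
#' Live entry weight times the live price, financed in full (by default) at
#' the annual rate over the feeding period.
#'
#' @param entry_weight Live entry weight, kg (> 0, vectorised).
#' @param params An [econ_params()].
#' @return Cost in ZAR.
#' @examples
#' purchase_cost(199.2, econ_params())
#' @export
purchase_cost <- function(entry_weight, params = econ_params()) {
  if (any(entry_weight <= 0))
    abort("entry_weight must be positive", class = "fl_domain_error")
  entry_weight * params$live_price *
    financing_multiplier(params$annual_interest_rate, params$days_on_feed,
                         params$day_count_basis, params$purchase_financed_fraction)
}

#' Feed cost over the feeding period (ledger line B)
#'
#' Base principal is daily intake x diet cost x days on feed; the financed
#' value adds simple interest on `feed_financed_fraction` of that principal
#' (half, by default: feed is bought continuously, so on average half the bill
#' accrues interest). The rate defaults to the feeding-line rate
#' (`feed_interest_rate_override` when set, else the annual rate).
#'
#' @param daily_intake Mean daily feed intake, kg/d (> 0, vectorised).
#' @param diet_cost Feed price, ZAR/kg (> 0).
#' @param params An [econ_params()].
#' @param rate Annual rate for the feed interest, fraction/yr.
#' @return A tibble with columns `base` and `financed`, ZAR.
#' @examples
#' feed_cost(8.69, 4.73, econ_params())
#' @export
feed_cost <- function(daily_intake, diet_cost, params = econ_params(),
                      rate = params$feed_interest_rate_override %||%
                        params$annual_interest_rate) {
  if (any(daily_intake <= 0) || any(diet_cost <= 0))
    abort("daily_intake and diet_cost must be positive", class = "fl_domain_error")
  base <- daily_intake * diet_cost * params$days_on_feed
  financed <- base * financing_multiplier(rate, params$days_on_feed,
                                          params$day_count_basis,
                                          params$feed_financed_fraction)
  tibble(base = base, financed = financed)
}

#' Total carcass cost (ledger line C)
#'
#' Purchase cost plus the feed principal financed at the canonical annual
#' rate (not the feeding-line override), keeping C, profit and margin
#' internally consistent.
#'
#' @param purchase Financed purchase cost A, ZAR.
#' @param base_feed Pre-interest feed principal, ZAR.
#' @param params An [econ_params()].
#' @return Total cost C, ZAR.
#' @export
total_cost <- function(purchase, base_feed, params = econ_params()) {
  if (any(purchase < 0) || any(base_feed < 0))
    abort("costs must be non-negative", class = "fl_domain_error")
  purchase + base_feed *
    financing_multiplier(params$annual_interest_rate, params$days_on_feed,
                         params$day_count_basis, params$feed_financed_fraction)
}

#' Carcass income (ledger line D)
#'
#' @param carcass_weight Carcass exit weight, kg (> 0).
#' @param carcass_price Sale price, ZAR/kg carcass.
#' @return Income in ZAR.
#' @export
carcass_income <- function(carcass_weight, carcass_price) {
  if (any(carcass_weight <= 0))
    abort("carcass_weight must be positive", class = "fl_domain_error")
  carcass_weight * carcass_price
}

#' Carcass feed cost of gain, CFCOG (ledger line E)
#'
#' Financed feed cost per kg of carcass gained over the feeding period — the
#' decision metric for matching diets to growth potential.
#'
#' @param financed_feed_cost Financed feed cost B, ZAR.
#' @param carcass_gain Carcass gain over the period, kg (> 0).
#' @return ZAR per kg carcass gain.
#' @export
cfcog <- function(financed_feed_cost, carcass_gain) {
  if (any(carcass_gain <= 0))
    abort("carcass_gain must be positive for a defined cost of gain",
          class = "fl_domain_error")
  financed_feed_cost / carcass_gain
}

#' Profit per animal (ledger line F)
#'
#' Income minus total cost; losses are legal (negative) outputs.
#'
#' @param income Carcass income D, ZAR.
#' @param cost Total cost C, ZAR.
#' @return Profit in ZAR.
#' @export
profit <- function(income, cost) income - cost

#' Profit margin on total cost (ledger line G)
#'
#' @param prof Profit F, ZAR.
#' @param cost Total cost C, ZAR (> 0).
#' @return Margin in percent.
#' @export
profit_margin <- function(prof, cost) {
  if (any(cost <= 0)) abort("cost must be positive", class = "fl_domain_error")
  100 * prof / cost
}

#' Calf:beef price ratio
#'
#' Live purchase price per kg divided by carcass sale price per kg, in
#' percent. A procurement guideline holds that this should stay under about
#' 55% for the feeding margin to carry the enterprise; South African markets
#' have recently run closer to 60%.
#'
#' @param live_price ZAR/kg live.
#' @param carcass_price ZAR/kg carcass (> 0).
#' @return Percent.
#' @examples
#' calf_beef_price_ratio(33.25, 55)
#' @export
calf_beef_price_ratio <- function(live_price, carcass_price) {
  if (any(carcass_price <= 0))
    abort("carcass_price must be positive", class = "fl_domain_error")
  100 * live_price / carcass_price
}

# Vectorised A-G ledger for cohort rows; the workhorse behind evaluate_grid()
# and the Monte-Carlo engine. `params$days_on_feed` is overridden per row by
# the cohort's own dof.
eval_cohort_econ <- function(cohorts, params = econ_params()) {
  stopifnot(nrow(cohorts) >= 1)
  dof <- cohorts$dof
  pmult <- financing_multiplier(params$annual_interest_rate, dof,
                                params$day_count_basis,
                                params$purchase_financed_fraction)
  fmult_c <- financing_multiplier(params$annual_interest_rate, dof,
                                  params$day_count_basis,
                                  params$feed_financed_fraction)
  rate_b <- params$feed_interest_rate_override %||% params$annual_interest_rate
  fmult_b <- financing_multiplier(rate_b, dof, params$day_count_basis,
                                  params$feed_financed_fraction)
  A <- cohorts$entry_wt_mean * params$live_price * pmult
  base_feed <- cohorts$dmi_mean * cohorts$diet_cost * dof
  B <- base_feed * fmult_b
  C <- A + base_feed * fmult_c
  D <- cohorts$carc_wt_mean * params$carcass_price
  E <- B / cohorts$gain_mean
  F_ <- D - C
  G <- 100 * F_ / C
  tibble(
    pp = cohorts$pp, diet = cohorts$diet, n = cohorts$n,
    purchase_cost_A = A,
    base_feed_cost = base_feed,
    feed_cost_B = B,
    total_cost_C = C,
    income_D = D,
    cfcog_E = E,
    profit_F = F_,
    margin_G = G,
    breakeven_live_price = (D - base_feed * fmult_c) /
      (cohorts$entry_wt_mean * pmult),
    breakeven_carcass_price = C / cohorts$carc_wt_mean
  )
}

#' Break-even live purchase price
#'
#' The live price per kg at which the cohort's profit is exactly zero with
#' every other parameter fixed: income less financed feed, spread over the
#' financed entry weight. Re-evaluating the ledger at the solved price
#' returns a profit within 0.01 ZAR of zero.
#'
#' @param cohorts A cohort table (see [read_cohorts()]).
#' @param params An [econ_params()].
#' @return A numeric vector, ZAR per kg live weight, one value per cohort row.
#' @examples
#' breakeven_live_price(builtin_table1())
#' @export
breakeven_live_price <- function(cohorts, params = econ_params()) {
  cohorts <- validate_cohorts(cohorts)
  eval_cohort_econ(cohorts, params)$breakeven_live_price
}

#' Break-even carcass sale price
#'
#' The carcass price per kg at which profit is zero: total cost divided by
#' carcass exit weight.
#'
#' @inheritParams breakeven_live_price
#' @return ZAR per kg carcass, one value per cohort row.
#' @export
breakeven_carcass_price <- function(cohorts, params = econ_params()) {
  cohorts <- validate_cohorts(cohorts)
  eval_cohort_econ(cohorts, params)$breakeven_carcass_price
}
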