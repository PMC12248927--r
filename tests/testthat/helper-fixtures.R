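# Shared fixtures: a minimal cohort builder and the published-ledger chain.

# one-row cohort with round, easily-checked values; override any field
make_cohort <- function(...) {
  base <- tibble::tibble(
    pp = "PP2", diet = "MPD", n = 10,
    entry_wt_mean = 200, entry_wt_lo = 190, entry_wt_hi = 210,
    carc_wt_mean = 280, carc_wt_lo = 270, carc_wt_hi = 290,
    cadg_mean = 1.0, cadg_lo = 0.9, cadg_hi = 1.1,
    cfcr_mean = 10, cfcr_lo = 9, cfcr_hi = 11,
    dmi_mean = 10, dmi_lo = 9, dmi_hi = 11,
    gain_mean = 150, gain_lo = 140, gain_hi = 160,
    dof = 142, diet_cost = 5
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# A-G ledger recomputed from the published purchase- and feeding-cost rows
# (the printed intermediates) through the package's own formulas. Returned as
# an fl_scenario so the comparison operations accept it.
exact_chain_scenario <- function(params = econ_params()) {
  t1 <- builtin_table1()
  t2 <- builtin_table2()
  mult_b <- financing_multiplier(
    params$feed_interest_rate_override, params$days_on_feed,
    params$day_count_basis, params$feed_financed_fraction)
  base <- t2$B / mult_b
  C <- total_cost(t2$A, base, params)
  D <- carcass_income(t1$carc_wt_mean, params$carcass_price)
  F <- profit(D, C)
  out <- tibble::tibble(
    pp = t1$pp, diet = t1$diet, n = t1$n,
    purchase_cost_A = t2$A, base_feed_cost = base, feed_cost_B = t2$B,
    total_cost_C = C, income_D = D, cfcog_E = cfcog(t2$B, t1$gain_mean),
    profit_F = F, margin_G = profit_margin(F, C),
    breakeven_live_price = NA_real_, breakeven_carcass_price = NA_real_
  )
  attr(out, "params") <- params
  class(out) <- c("fl_scenario", class(out))
  out
}
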