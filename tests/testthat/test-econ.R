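test_that("simple pro-rata financing multiplier", {
  expect_equal(financing_multiplier(0, 142), 1)
  expect_equal(financing_multiplier(0.1175, 142, 365, 1),
               1 + 0.1175 * 142 / 365)
  expect_equal(financing_multiplier(0.1175, 142, 365, 1), 1.045712, tolerance = 1e-6)
  expect_equal(financing_multiplier(0.1175, 142, 365, 0.5), 1.022856, tolerance = 1e-6)
  expect_error(financing_multiplier(-0.1, 142), class = "fl_domain_error")
  expect_error(financing_multiplier(0.1, -1), class = "fl_domain_error")
  expect_error(financing_multiplier(0.1, 142, 365, 1.5), class = "fl_domain_error")
})

test_that("financed purchase cost reproduces the published A row", {
  p <- econ_params()
  expect_equal(purchase_cost(199.2, p), 6926.17, tolerance = 0.005 / 6926)
  expect_equal(purchase_cost(229.4, p), 7976.22, tolerance = 0.02 / 7976)
  # zero-interest identity
  p0 <- econ_params(annual_interest_rate = 0)
  w <- runif(5, 150, 300)
  expect_equal(purchase_cost(w, p0), w * 33.25, tolerance = 1e-12)
  expect_error(purchase_cost(-1, p), class = "fl_domain_error")
})

test_that("feed cost: base principal and financed value", {
  p <- econ_params()
  fc <- feed_cost(8.69, 4.73, p)  # feeding-line rate 10% by default
  expect_equal(fc$base, 8.69 * 4.73 * 142)
  expect_equal(fc$base, 5836.73, tolerance = 0.01 / 5836)
  expect_equal(fc$financed, 5951.52, tolerance = 0.001)  # printed value, intake rounded
  fc0 <- feed_cost(8.69, 4.73, p, rate = 0)
  expect_equal(fc0$financed, fc0$base)
  expect_error(feed_cost(0, 4.73, p), class = "fl_domain_error")
})

test_that("total cost finances feed at the canonical rate", {
  p <- econ_params()
  mult_b <- financing_multiplier(0.10, 142, 365, 0.5)
  expect_equal(total_cost(6926.17, 5951.52 / mult_b, p), 12897.56, tolerance = 0.05 / 12897)
  expect_equal(total_cost(7360.80, 7580.66 / mult_b, p), 14966.77, tolerance = 0.05 / 14966)
  expect_equal(total_cost(5000, 0, p), 5000)
})

test_that("income, cost of gain, profit and margin lines", {
  expect_equal(carcass_income(231.1, 55), 12710.50)
  expect_equal(carcass_income(285.2, 55), 15686.00)
  expect_equal(carcass_income(100, 0), 0)
  expect_error(carcass_income(0, 55), class = "fl_domain_error")

  expect_equal(cfcog(7580.66, 165.0), 45.94, tolerance = 0.005 / 45.94)
  expect_equal(cfcog(7663.69, 156.6), 48.94, tolerance = 0.005 / 48.94)
  expect_equal(cfcog(123.4, 123.4), 1)
  expect_error(cfcog(1000, 0), class = "fl_domain_error")

  expect_equal(profit(15686.00, 14966.77), 719.23)
  expect_equal(profit(14228.50, 14929.28), -700.78)
  expect_equal(profit(100, 100), 0)

  expect_equal(profit_margin(719.23, 14966.77), 4.81, tolerance = 0.005 / 4.81)
  expect_equal(profit_margin(251.35, 17299.15), 1.45, tolerance = 0.005 / 1.45)
  expect_equal(profit_margin(0, 1000), 0)
  expect_error(profit_margin(10, 0), class = "fl_domain_error")
})

test_that("calf:beef price ratio", {
  expect_equal(calf_beef_price_ratio(33.25, 55), 60.45, tolerance = 1e-3)
  expect_equal(calf_beef_price_ratio(55, 55), 100)
  expect_equal(calf_beef_price_ratio(0, 55), 0)
  expect_error(calf_beef_price_ratio(33, 0), class = "fl_domain_error")
})

test_that("ledger identities hold exactly on every evaluation", {
  set.seed(7)
  for (i in 1:15) {
    p <- econ_params(
      live_price = runif(1, 20, 50), carcass_price = runif(1, 40, 70),
      annual_interest_rate = runif(1, 0, 0.3),
      feed_interest_rate_override = if (i %% 2) runif(1, 0, 0.2) else NULL)
    ew <- runif(1, 150, 300); cw <- runif(1, 250, 350)
    dm <- runif(1, 7, 13); gn <- runif(1, 100, 200)
    co <- make_cohort(entry_wt_mean = ew, entry_wt_lo = ew - 5, entry_wt_hi = ew + 5,
                      carc_wt_mean = cw, carc_wt_lo = cw - 5, carc_wt_hi = cw + 5,
                      dmi_mean = dm, dmi_lo = dm - 1, dmi_hi = dm + 1,
                      gain_mean = gn, gain_lo = gn - 5, gain_hi = gn + 5)
    g <- evaluate_grid(co, p)
    fmult <- financing_multiplier(p$annual_interest_rate, co$dof,
                                  p$day_count_basis, p$feed_financed_fraction)
    expect_equal(g$total_cost_C, g$purchase_cost_A + g$base_feed_cost * fmult,
                 tolerance = 1e-12)
    expect_equal(g$profit_F, g$income_D - g$total_cost_C, tolerance = 1e-12)
    expect_equal(g$margin_G, 100 * g$profit_F / g$total_cost_C, tolerance = 1e-12)
  }
})

test_that("profit responds monotonically to prices, feed cost and interest", {
  co <- builtin_table1()[5, ]
  prof <- function(...) evaluate_grid(co, econ_params(...))$profit_F
  live <- sapply(seq(25, 45, by = 2), function(x) prof(live_price = x))
  expect_true(all(diff(live) < 0))
  carc <- sapply(seq(45, 65, by = 2), function(x) prof(carcass_price = x))
  expect_true(all(diff(carc) > 0))
  rate <- sapply(seq(0, 0.3, by = 0.05), function(x)
    prof(annual_interest_rate = x, feed_interest_rate_override = NULL))
  expect_true(all(diff(rate) < 0))
  dcost <- sapply(seq(3, 8, by = 0.5), function(x)
    evaluate_grid(make_cohort(diet_cost = x), econ_params())$profit_F)
  expect_true(all(diff(dcost) < 0))
})

test_that("break-even prices zero the profit for every study cohort", {
  t1 <- builtin_table1()
  p <- econ_params()
  be_live <- breakeven_live_price(t1, p)
  be_carc <- breakeven_carcass_price(t1, p)
  for (i in seq_len(nrow(t1))) {
    p_live <- econ_params(live_price = be_live[i])
    expect_lt(abs(evaluate_grid(t1[i, ], p_live)$profit_F), 0.01)
    p_carc <- econ_params(carcass_price = be_carc[i])
    expect_lt(abs(evaluate_grid(t1[i, ], p_carc)$profit_F), 0.01)
  }
})

test_that("break-even solutions agree with an independent root finder", {
  t1 <- builtin_table1()
  p <- econ_params()
  for (i in c(1, 5, 9)) {
    root_live <- stats::uniroot(function(x)
      evaluate_grid(t1[i, ], econ_params(live_price = x))$profit_F,
      c(1, 200), tol = 1e-9)$root
    expect_equal(breakeven_live_price(t1[i, ], p), root_live, tolerance = 1e-6)
    root_carc <- stats::uniroot(function(x)
      evaluate_grid(t1[i, ], econ_params(carcass_price = x))$profit_F,
      c(1, 200), tol = 1e-9)$root
    expect_equal(breakeven_carcass_price(t1[i, ], p), root_carc, tolerance = 1e-6)
  }
})

test_that("break-even closed forms match the published-intermediate arithmetic", {
  p <- econ_params()
  mult_b <- financing_multiplier(0.10, 142, 365, 0.5)
  mult_c <- financing_multiplier(0.1175, 142, 365, 0.5)
  mult_a <- financing_multiplier(0.1175, 142, 365, 1)
  # cohort whose intake reproduces the published PP2/MPD feeding cost
  co <- builtin_table1()[5, ]
  co$dmi_mean <- 7580.66 / mult_b / (5.10 * 142)
  expect_equal(breakeven_live_price(co, p),
               (15686.00 - 7580.66 / mult_b * mult_c) / (211.7 * mult_a),
               tolerance = 1e-9)
  expect_equal(breakeven_live_price(co, p), 36.50, tolerance = 0.005 / 36.5)
  # break-even is a fixed point when profit is already zero
  be <- breakeven_live_price(co, p)
  expect_equal(breakeven_live_price(co, econ_params(live_price = be)), be,
               tolerance = 1e-10)
  # carcass-price dual: C / carcass weight, halves when weight doubles
  co2 <- builtin_table1()[7, ]
  C <- evaluate_grid(co2, p)$total_cost_C
  expect_equal(breakeven_carcass_price(co2, p), C / 258.7, tolerance = 1e-10)
  co2_big <- co2
  co2_big$carc_wt_mean <- co2$carc_wt_mean * 2
  co2_big$carc_wt_hi <- co2$carc_wt_hi * 3
  expect_equal(breakeven_carcass_price(co2_big, p),
               breakeven_carcass_price(co2, p) / 2, tolerance = 1e-10)
})

test_that("config reader builds validated parameters", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("live_price: 30.0", "annual_interest_rate: 0.10"), path)
  p <- read_econ_params(path)
  expect_equal(p$live_price, 30)
  expect_equal(p$carcass_price, 55)   # default retained
  writeLines("no_such_field: 1", path)
  expect_error(read_econ_params(path), "no_such_field", class = "fl_param_error")
  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('{"carcass_price": 60}', jpath)
  expect_equal(read_econ_params(jpath)$carcass_price, 60)
  expect_error(econ_params(feed_financed_fraction = 1.2), class = "fl_param_error")
  expect_error(econ_params(day_count_basis = 364), class = "fl_param_error")
})
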