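test_that("default trial reproduces the experimental structure", {
  recs <- generate_trial(trial_design(seed = 1))
  expect_equal(nrow(recs), 108)                       # 27 animals x 4 PP classes
  expect_equal(length(unique(recs$pen_id)), 36)       # 9 pens per PP class
  counts <- table(recs$pp)
  expect_true(all(counts == 27))
  cell_counts <- table(recs$pp, recs$diet)
  expect_true(all(cell_counts == 9))
  pen_sizes <- table(table(recs$pen_id))
  expect_equal(unname(pen_sizes[c("1", "4")]), c(12, 24), ignore_attr = TRUE)
  # each diet within a PP gets one solitary pen and two pens of four
  per_cell <- tapply(recs$pen_id, paste(recs$pp, recs$diet), function(p)
    sort(as.vector(table(p))))
  expect_true(all(vapply(per_cell, identical, logical(1), c(1L, 4L, 4L))))
  expect_equal(unique(recs$days_on_feed), 142)
  expect_true(all(recs$entry_weight > 0 & recs$exit_carcass_weight > 0 &
                    recs$total_intake > 0))
})

test_that("generation is deterministic under the design seed", {
  a <- generate_trial(trial_design(seed = 42))
  b <- generate_trial(trial_design(seed = 42))
  expect_identical(a, b)
  c <- generate_trial(trial_design(seed = 43))
  expect_false(identical(a, c))
})

test_that("degenerate designs and impossible partitions", {
  solo <- trial_design(pp_classes = "PP2", diets = "MPD", pen_sizes = 1, seed = 2)
  recs <- generate_trial(solo)
  expect_equal(nrow(recs), 1)
  expect_error(trial_design(pen_sizes = c(1, 4, 4)),
               "impossible pen partition", class = "fl_validation_error")
  expect_error(trial_design(intake_gain_cor = 1.5), class = "fl_validation_error")
  expect_error(trial_design(dropout = 1), class = "fl_validation_error")
  few <- generate_trial(trial_design(seed = 9, dropout = 0.5))
  expect_lt(nrow(few), 108)
})

test_that("zero-variance generators reproduce their means exactly", {
  gens <- default_trait_generators()
  gens$entry$sd[] <- 0
  gens$cell$gain_sd[] <- 0
  gens$cell$dmi_sd[] <- 0
  d <- trial_design(pp_classes = c("PP1", "PP3"), trait_generators = gens, seed = 4)
  recs <- generate_trial(d)
  co <- summarize_to_cohorts(recs)
  for (pp in c("PP1", "PP3")) {
    expect_equal(unique(recs$entry_weight[recs$pp == pp]),
                 gens$entry$mean[gens$entry$pp == pp], tolerance = 1e-12)
    for (diet in c("LPD", "MPD", "HPD")) {
      row <- co[co$pp == pp & co$diet == diet, ]
      gen <- gens$cell[gens$cell$pp == pp & gens$cell$diet == diet, ]
      expect_equal(row$gain_mean, gen$gain_mean, tolerance = 1e-10)
      expect_equal(row$dmi_mean, gen$dmi_mean, tolerance = 1e-10)
      expect_equal(row$gain_lo, row$gain_hi)   # zero-width interval
    }
  }
})

test_that("cohort means recover generator parameters at large n", {
  gens <- default_trait_generators()
  d <- trial_design(pp_classes = c("PP1", "PP3"),
                    pen_sizes = rep(4, 7500),      # 10,000 animals per cell
                    trait_generators = gens, seed = 6)
  recs <- generate_trial(d)
  co <- summarize_to_cohorts(recs)
  expect_equal(unique(co$n), 10000)
  for (i in seq_len(nrow(co))) {
    gen <- gens$cell[gens$cell$pp == co$pp[i] & gens$cell$diet == co$diet[i], ]
    expect_equal(co$gain_mean[i], gen$gain_mean, tolerance = 0.01)
    expect_equal(co$dmi_mean[i], gen$dmi_mean, tolerance = 0.01)
    epar <- gens$entry[gens$entry$pp == co$pp[i], ]
    expect_equal(co$entry_wt_mean[i], epar$mean, tolerance = 0.01)
    # SDs recovered through the t-interval within 5%
    expect_equal(sd_from_ci(co$gain_lo[i], co$gain_hi[i], co$n[i]),
                 gen$gain_sd, tolerance = 0.05)
    expect_equal(sd_from_ci(co$entry_wt_lo[i], co$entry_wt_hi[i], co$n[i]),
                 epar$sd, tolerance = 0.05)
  }
})

test_that("replicate trials keep the average-class entry mean inside the published interval", {
  # PP2/MPD published mean entry weight 211.7, 95% CI (200.2, 223.2)
  hits <- vapply(1:200, function(s) {
    recs <- generate_trial(trial_design(pp_classes = c("PP2+", "PP2-"), seed = s))
    m <- mean(recs$entry_weight[recs$diet == "MPD"])
    m >= 200.2 && m <= 223.2
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("aggregation level changes the feed conversion ratio (Jensen gap)", {
  # two pens, equal intake, unequal gains: mean of per-pen ratios exceeds the
  # ratio of totals because the ratio is convex in the gain
  recs <- tibble::tibble(
    animal_id = c("A1", "A2"), pp = "PP2", diet = "MPD",
    pen_id = c("p1", "p2"),
    entry_weight = c(200, 200),
    exit_carcass_weight = entry_carcass_weight(c(200, 200)) + c(100, 200),
    total_intake = c(1420, 1420), days_on_feed = 142
  )
  mor <- summarize_to_cohorts(recs, "mean_of_ratios")
  rom <- summarize_to_cohorts(recs, "ratio_of_means")
  # brute-force arithmetic oracle
  expect_equal(mor$cfcr_mean, mean(c(1420 / 100, 1420 / 200)))
  expect_equal(rom$cfcr_mean, 2840 / 300)
  expect_gt(mor$cfcr_mean, rom$cfcr_mean)
  expect_equal(mor$cadg_mean, rom$cadg_mean)  # arithmetic means agree here
})

test_that("single-animal cells flag undefined intervals", {
  recs <- generate_trial(trial_design(pp_classes = "PP2", diets = "MPD",
                                      pen_sizes = 1, seed = 12))
  co <- summarize_to_cohorts(recs)
  expect_equal(co$entry_wt_lo, co$entry_wt_hi)
  expect_equal(attr(co, "ci_undefined"), "PP2 MPD")
})

test_that("generated trials flow through pooling and the economic grid", {
  recs <- generate_trial(trial_design(seed = 31))
  co <- summarize_to_cohorts(recs)
  expect_equal(nrow(co), 12)
  g <- evaluate_grid(co)
  expect_equal(nrow(g), 12)
  pooled <- pool_pp2_cells(co)
  expect_equal(nrow(pooled), 9)
  expect_setequal(unique(pooled$pp), c("PP1", "PP2", "PP3"))
  expect_equal(nrow(evaluate_grid(pooled)), 9)
  # records round-trip through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_animal_records(recs, path)
  back <- read_animal_records(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))
})
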