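---
title: "The carcass-basis break-even model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The carcass-basis break-even model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedlotprofit)
```

## The problem

A beef feedlot buys a weaner calf by live weight, feeds it for a fixed
period, and sells a carcass by carcass weight. Its profit per animal is
driven almost entirely by two inputs — the calf purchase price and the feed
bill — and by how efficiently feed becomes *carcass* gain, not live gain,
because beef trades on a carcass basis. `feedlotprofit` models this for
cohorts of calves classified into phenotypic production profiles (PP 1
above-average, PP 2 average, PP 3 below-average growth potential) and fed
diets of increasing nutrient specification (LPD, MPD, HPD). The question the
model answers is a precision-feeding one: which diet best matches each calf
class, measured by the carcass feed cost of gain (CFCOG) and by profit per
head?

## The deterministic ledger

Every cohort is one row of production data: mean live entry weight, mean
daily feed intake, carcass exit weight and carcass gain over the feeding
period, plus the diet price. The economics are seven pure functions of that
row (see `evaluate_grid()`):

| line | meaning | formula |
|------|---------|---------|
| A | financed purchase cost | `W · p_l · (1 + r·d/b)` |
| B | financed feeding cost | `I · c · d · (1 + ½·r_B·d/b)` |
| C | total carcass cost | `A + I·c·d · (1 + ½·r·d/b)` |
| D | carcass income | `CW_exit · p_c` |
| E | carcass feed cost of gain | `B / ΔCW` |
| F | profit per animal | `D − C` |
| G | profit margin | `100 · F / C` |

with `W` entry weight (kg), `I` intake (kg/d), `c` diet cost (ZAR/kg), `d`
days on feed, `b` the day-count basis (days/yr), `p_l`/`p_c` the live and
carcass prices (ZAR/kg), `CW_exit` carcass exit weight and `ΔCW` carcass
gain (kg).

Interest is **simple pro-rata**: a principal financed for `d` of `b` days at
annual rate `r` grows by `1 + r·d/b`, with only a fraction of the principal
financed (all of the purchase; half of the feed, since feed is bought
continuously through the period and on average half the bill accrues
interest). This convention — not compound interest — reproduces the study's
financed purchase costs to the cent, which is how it was identified.

Only purchase and feed are modelled. Yard, health and fixed costs were
identical across the study's cohorts, so they cancel from every within-study
comparison; absolute profits should be read with that in mind.

### Two feed-interest rates

The published ledger is internally consistent only under two rates: its
feeding-cost line (and therefore CFCOG) carries interest at 10%/yr, while
its total-cost line finances the same feed principal at the 11.75%/yr used
for the purchase. The package makes the 11.75% rate canonical — `C`, `F` and
`G` form an exact identity chain — and exposes the feeding-line rate as
`feed_interest_rate_override` (default `0.10`) so line B and CFCOG match the
reported convention. Setting the override to `NULL` finances everything at
the single canonical rate.

### The live-to-carcass conversion

Entry carcass weight is predicted from shrunk body weight as
`CW = 0.694·SBW − 38.43` kg (`entry_carcass_weight()`). Inputs at or below
the root (55.375 kg) are rejected rather than clamped. Cohort-level carcass
gain is taken as *input data*, not recomputed as exit weight minus converted
entry weight: the study's printed gains are per-animal aggregates that the
conversion of cohort means does not reproduce (e.g. the weakest class on
the cheapest diet: 231.1 − 99.81 = 131.3 kg versus the recorded 119.5 kg).
The conversion is still used wherever the package must *construct* carcass
weights — in the synthetic generator — keeping generated records internally
consistent.

Similarly, the study's printed feed conversion ratios differ from the ratio
of its printed cohort means (10.62 vs 10.33 for PP 3/LPD), a signature of
mean-of-per-pen-ratios aggregation. `summarize_to_cohorts()` therefore
offers both aggregations, with `mean_of_ratios` the default (it is what a
feedlot recording per-pen bunks actually measures); the two differ by a
Jensen gap whenever per-pen gains vary.

## Parameters that matter

* `live_price` (33.25 ZAR/kg live) and `carcass_price` (55.00 ZAR/kg):
  the market prices of the study period. Their ratio, 60.5%
  (`calf_beef_price_ratio()`), sits above the ~55% procurement guideline —
  a structurally expensive calf market.
* `annual_interest_rate` (0.1175/yr): the prime-linked financing rate.
* `feed_interest_rate_override` (0.10/yr): the feeding-line rate above.
* `days_on_feed` (142 d) and `day_count_basis` (365): the financing window.
* Diet costs (4.73 / 5.10 / 6.10 ZAR/kg for LPD / MPD / HPD): actual costs
  of the experimental facility, above the industry norm.

Break-even prices come from the linearity of the ledger: profit is affine in
each price, so `breakeven_live_price()` and `breakeven_carcass_price()` are
closed forms, verified in the tests against an independent root finder and by
the round-trip property |F(solved price)| < 0.01 ZAR.

## Uncertainty propagation

The study reports trait means with 95% confidence intervals, not SDs.
`sd_from_ci()` inverts the t-based interval,
`sd = √n·(hi − lo)/(2·t₀.₉₇₅,ₙ₋₁)`; if the source intervals were z-based the
SDs are overestimated by `t/1.96` (≈ 18% at n = 9), which makes the profit
distributions conservative. Whether the intervals describe animals or pens
is equally unstated; the package treats `n` as independent units.

`monte_carlo()` draws entry weight, carcass exit weight, daily intake and
carcass gain **independently** (no covariances are published; intake and
gain are positively correlated in reality, so simulated profit variance is
again conservative — correlated income and feed-cost errors partially
cancel) and pushes each draw through the full-precision ledger. Numerical
choices:

* **Antithetic pairing** `(z, −z)` is the default. Profit is exactly linear
  in all four sampled traits, so antithetic pairs average to the
  deterministic profit to machine precision — the simulated mean is unbiased
  by construction and all Monte-Carlo error concentrates in the spread and
  tail summaries, where it belongs. `antithetic = FALSE` gives plain
  independent sampling (the mean then converges at the usual `sd/√n` rate).
* Draws with any non-positive trait are rejected and redrawn (a carcass
  that shrank has no defined economics); the rejection fraction is reported
  and flagged above 10%. Under the study's parameters no draws are rejected.
* The RNG is Mersenne-Twister with inversion normals, recorded in the
  summary (`rng_kind`) so identical seeds are reproducible across sessions.
* A lognormal family (moment-matched) is available for strictly positive
  traits; the default is normal, matching the symmetric published intervals.

`oat_sensitivity()` perturbs one input by ±δ and reports the central
difference elasticity; because the ledger is affine in prices, the price
elasticities are exact at any δ.

## The synthetic generator

`generate_trial()` emulates the source experiment's structure: per PP class,
27 animals in three solitary pens and six pens of four, ranked by entry
weight and randomised to the three diets within rank blocks of three, 142
days on feed. Defaults are fixed to the study conditions:

* Entry weight is drawn per PP class (it precedes diet allocation), using
  the n-weighted mean and pooled SD of that class's published cells.
* Gain and intake are drawn per (PP, diet) cell from the published means and
  CI-derived SDs, with correlation 0.5 between an animal's gain and intake —
  a realistic positive coupling that deliberately violates the independence
  assumption of the uncertainty module, so tests can probe it; set
  `intake_gain_cor = 0` to match that module's assumption.
* PP 2+ and PP 2− are generated from the pooled PP 2 parameters with a ±3%
  gain-mean offset and re-pooled by `pool_pp2()` (n-weighted means, pooled
  variance), mirroring how the study combined them. The published tables
  only constrain the pooled class, so the offset is a modelling choice of
  plausible within-class spread.
* Dropout defaults to 0. The published cell sizes (8–18) are inconsistent
  with 27 animals per class over 3 diets and no exclusions are described; a
  `dropout` parameter exists for exploring that, but reproduction runs keep
  every animal.

What the generator does **not** emulate: mechanistic growth or intake
dynamics, pen-environment effects, disease or mortality, and market price
variation. Passing tests on synthetic data therefore demonstrate the
pipeline's statistical correctness (parameter recovery, aggregation effects,
seeded determinism), not biological realism.

## Numerical conventions and degenerate inputs

* No rounding inside any computation; rendering to the published layout
  (`render_table2()`) rounds to 2 decimals with ASCII minus signs, and is
  pure presentation — re-parsing a rendered report recovers the ledger to
  print precision.
* Currency comparisons in tests use 0.01 ZAR absolute tolerance unless the
  printed rounding of an input dominates.
* Negative profits are legal outputs everywhere; non-positive gains,
  weights, intakes or total costs are domain errors, not NaNs.
* Ties in `best_diet_per_pp()` break toward the cheaper diet, then
  alphabetically, so the result is order-invariant.
* A one-animal (or one-pen) cell has no within-cell variance; its intervals
  are reported zero-width and the cell is listed in the `ci_undefined`
  attribute.
* One published table cell is garbled in the source (the PP 1/HPD carcass
  weight); it is read as mean 319.1 with interval (305.1, 333.1), the only
  reading consistent with that cohort's income and profit lines. The
  published income cell for the same cohort (17,550.00) disagrees by 0.50
  ZAR with its own profit row and is treated as the misprint.

## Problem sizes used in the checks

The shipped tests evaluate the nine-cohort study grid (milliseconds),
Monte-Carlo runs of 10⁵ draws per cohort (seconds for all nine), and
synthetic trials of 10⁴ animals per cell for parameter recovery — sizes at
which the stochastic checks have comfortable margins (a 10⁴-animal mean
estimates its generator mean to ~0.1%) while the whole suite runs in well
under a minute.

## Known limitations

* Only purchase and feed costs are modelled; the ledger is a comparison
  tool, not a full enterprise budget.
* The two unexplained figures in the source narrative (a 13.74% feed-cost
  difference and a 49.6% loss reduction) cannot be derived from any
  combination of the published table rows; the package reproduces the
  tables and the recoverable comparative claims (e.g. the 14% margin
  improvement of LPD over MPD for PP 3 calves) but does not attempt those
  two.
* Trait independence and t-based interval inversion are assumptions, both
  conservative for profit variance, as discussed above.
* Prices are constants; no market dynamics, and no profit-maximising diet
  reformulation — the model evaluates given diets, it does not design them.
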