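# feedlotprofit

Carcass-basis break-even economics for beef feedlot cohorts.

South African feedlots buy weaner calves by live weight and sell carcasses by
carcass weight, so the margin a calf earns depends on how cheaply feed is
turned into *carcass* gain. `feedlotprofit` implements a deterministic
break-even profitability model on that carcass basis for cohorts of feeder
calves classified by phenotypic production profile (PP 1 above-average, PP 2
average, PP 3 below-average growth potential) and finished on diets of
increasing specification (LPD, MPD, HPD). It is aimed at feedlot economists
and production researchers who want to compare diets within calf classes,
solve procurement break-evens, and propagate trait uncertainty into profit
distributions.

## The model

For a cohort with mean live entry weight `W` (kg), mean daily intake `I`
(kg/d), carcass exit weight `CW_exit` (kg) and carcass gain `ΔCW` (kg) over
`d` days on feed, with live price `p_l` (ZAR/kg), carcass price `p_c`
(ZAR/kg), diet cost `c` (ZAR/kg) and simple pro-rata interest at annual rate
`r` (ACT/365):

```
A = W · p_l · (1 + r·d/365)              financed purchase cost
B = I · c · d · (1 + ½·r_B·d/365)        financed feed cost (half the feed
                                         principal accrues interest)
C = A + I · c · d · (1 + ½·r·d/365)      total carcass cost
D = CW_exit · p_c                        carcass income
E = B / ΔCW                              carcass feed cost of gain (CFCOG)
F = D − C                                profit per animal
G = 100 · F / C                          profit margin (%)
```

Live entry weight converts to entry carcass weight through the linear
relationship `CW = 0.694·SBW − 38.43` kg. Two interest rates coexist by
design: the feeding-cost line `B` (and hence CFCOG) is financed at the
feeding-line rate `r_B` (default 10%/yr), while the total cost `C` finances
feed at the canonical rate `r` (default 11.75%/yr), which keeps `C`, `F` and
`G` internally consistent. Break-even solvers invert `F = 0` for the live
purchase price and the carcass sale price in closed form, a Monte-Carlo
engine propagates trait 95% CIs into profit distributions, and a seeded
generator produces pen-level synthetic trials (4 PP classes × 3 diets, three
solitary pens plus six pens of four per class, 142 days on feed).

## Worked example

```r
library(feedlotprofit)

grid <- evaluate_grid(builtin_table1(), econ_params())
subset(as.data.frame(grid), diet == "MPD",
       select = c(pp, total_cost_C, income_D, cfcog_E, profit_F, margin_G))
#>    pp total_cost_C income_D  cfcog_E   profit_F  margin_G
#> 4 PP3     14139.29  13893.0 50.97072 -246.28560 -1.741853
#> 5 PP2     14975.73  15686.0 45.99753  710.26975  4.742806
#> 6 PP1     16146.72  16560.5 48.32823  413.77758  2.562610
```

On the medium-production diet (the industry norm) the average PP 2 calf is
the only clear winner: it earns about 710 ZAR per head at the lowest feed
cost of gain (46.00 ZAR per kg of carcass), while the below-average PP 3 calf
loses about 246 ZAR. Which diet limits that loss, and at what purchase price
would PP 3 break even?

```r
best_diet_per_pp(grid, "profit_F")
#>   pp    diet  profit_F
#> 1 PP1   MPD       414.
#> 2 PP2   MPD       710.
#> 3 PP3   LPD      -186.

breakeven_live_price(builtin_table1()[4, ])   # PP3 on MPD
#> [1] 32.0724  (ZAR/kg live; paid price was 33.25)

mc <- monte_carlo(builtin_table1()[5, ], n_draws = 1e5, seed = 42)
mc
#> <fl_mc> PP2 / MPD: 100000 draws (seed 42, normal, antithetic)
#>   profit mean 710.27 ZAR (deterministic 710.27), sd 1915.26
#>   95% interval [-3041.83, 4462.37], P(loss) = 0.357
```

The cheapest (low-production) diet trims the PP 3 loss by about a quarter
(−246 to −186 ZAR), and even the most profitable cohort carries a ~36%
probability of loss once the published trait variation is propagated through
the ledger.

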