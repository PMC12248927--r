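Package: feedlotprofit
Title: Carcass-Basis Break-Even Economics for Beef Feedlot Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic break-even profitability modelling of beef feedlot
    cohorts on a carcass basis: financed purchase and feed costs under simple
    pro-rata interest, carcass income, carcass feed cost of gain (CFCOG),
    profit and margin ledgers per production-profile class and diet, with
    break-even price solvers, one-at-a-time sensitivity, Monte-Carlo
    propagation of trait confidence intervals into profit distributions, and
    a seeded pen-level synthetic trial generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
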