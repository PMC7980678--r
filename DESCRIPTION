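Package: promoscan
Title: Household Exposure to Retail Price Promotions and Beverage Purchases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how temporary retail price reductions on
    sugar-sweetened beverages relate to household purchasing. Detects price
    promotions in weekly store scanner data as discounts from modal (most
    frequently observed) prices, derives household-level annual promotion
    frequency and magnitude from the stores each household shopped at, links
    exposure to consumer-panel purchase records, and fits adjusted log-linear
    models of annual per-capita purchase volume with subgroup interaction
    tests. Includes a seeded synthetic scanner-and-panel data generator with
    planted promotion effects, and a study runner covering the full
    sensitivity grid over promotion thresholds, store-aggregation rules and
    panel-coverage filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
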