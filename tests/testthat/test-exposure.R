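test_that("modal price is the most frequent price, ties broken upward", {
  prices <- tibble::tibble(
    store_id = "s1", product_id = "p1",
    week_index = 1:52,
    unit_price = c(rep(1.00, 40), rep(0.90, 12))
  )
  expect_equal(compute_modal_prices(prices)$modal_unit_price, 1.00)

  tie <- prices
  tie$unit_price <- c(rep(1.00, 26), rep(0.90, 26))
  expect_equal(compute_modal_prices(tie)$modal_unit_price, 1.00)

  single <- prices[1, ]
  single$unit_price <- 0.99
  expect_equal(compute_modal_prices(single)$modal_unit_price, 0.99)
})

test_that("weekly discount is the clamped fraction off the modal price", {
  expect_equal(weekly_discount(0.95, 1.00), 0.05)
  expect_equal(weekly_discount(1.10, 1.00), 0.00)
  expect_equal(weekly_discount(1.80, 2.00), 0.10)
  expect_error(weekly_discount(0, 1), "strictly positive")
  expect_error(weekly_discount(1, -2), "strictly positive")
})

test_that("store-week magnitude is the weight-renormalised mean discount", {
  weights <- tibble::tibble(product_id = c("pA", "pB"), weight = c(0.5, 0.5))
  prices <- tibble::tibble(
    store_id = "s1", week_index = c(1L, 1L, 2L),
    product_id = c("pA", "pB", "pA"),
    unit_price = c(0.90, 1.00, 0.92)
  )
  modal <- tibble::tibble(
    store_id = "s1", product_id = c("pA", "pB"),
    modal_unit_price = c(1.00, 1.00)
  )
  sw <- store_week_magnitude(prices, weights, modal)
  # week 1: both observed, discounts 0.10 and 0 -> 0.05
  expect_equal(sw$magnitude[sw$week_index == 1], 0.05)
  # week 2: only pA observed, discount 0.08 -> renormalised to 0.08
  expect_equal(sw$magnitude[sw$week_index == 2], 0.08)
  # all discounts zero -> 0
  flat <- prices
  flat$unit_price <- 1.00
  sw0 <- store_week_magnitude(flat, weights, modal)
  expect_true(all(sw0$magnitude == 0))
  # zero-weight-only store-weeks fall back to the plain mean
  w0 <- tibble::tibble(product_id = c("pA", "pB"), weight = c(0, 1))
  sw2 <- store_week_magnitude(prices, w0, modal)
  expect_equal(sw2$magnitude[sw2$week_index == 2], 0.08)
})

test_that("household-week exposure aggregates the store set", {
  sw <- tibble::tibble(
    store_id = c("s1", "s2"), week_index = 1L, magnitude = c(0.02, 0.08)
  )
  sets <- tibble::tibble(household_id = "h1", store_id = c("s1", "s2"))
  cfg <- function(agg) exposure_config(aggregation = agg, n_weeks = 2)
  largest <- household_week_exposure(sw, sets, cfg("largest"))
  average <- household_week_exposure(sw, sets, cfg("average"))
  expect_equal(largest$magnitude[largest$week_index == 1], 0.08)
  expect_equal(average$magnitude[average$week_index == 1], 0.05)
  # week with no observed magnitude scores zero, keeping 2 weeks per household
  expect_equal(largest$magnitude[largest$week_index == 2], 0)
  expect_equal(nrow(largest), 2)

  single <- tibble::tibble(household_id = "h1", store_id = "s1")
  for (mode in c("largest", "average")) {
    one <- household_week_exposure(sw, single, cfg(mode))
    expect_equal(one$magnitude[one$week_index == 1], 0.02)
  }
  expect_error(
    household_week_exposure(sw, sets[0, ], cfg("largest")),
    "empty"
  )
})

test_that("annualisation counts threshold weeks and averages all weeks", {
  cfg <- exposure_config(promo_threshold = 0.05)
  a <- annualize(weekly_tbl(c(rep(0.06, 23), rep(0, 29))), cfg)
  expect_equal(a$frequency, 23 / 52)
  expect_equal(a$magnitude, 23 * 0.06 / 52)

  expect_equal(annualize(weekly_tbl(rep(0, 52)), cfg)$frequency, 0)
  expect_equal(annualize(weekly_tbl(rep(0, 52)), cfg)$magnitude, 0)

  # the threshold comparison is inclusive
  at <- annualize(weekly_tbl(rep(0.05, 52)), cfg)
  expect_equal(at$frequency, 1.0)
  expect_equal(at$magnitude, 0.05)

  expect_error(annualize(weekly_tbl(rep(0, 51)), cfg), "51 weekly values")
})

test_that("exposure invariants hold on random instances", {
  for (seed in 1:25) {
    inst <- random_instance(seed + 1000)
    sw <- store_week_magnitude(inst$prices, inst$weights)
    sets <- household_store_sets(inst$purchases, inst$stores)
    if (nrow(sets) == 0) next
    cfg_l <- exposure_config(aggregation = "largest", n_weeks = inst$n_weeks)
    cfg_a <- exposure_config(aggregation = "average", n_weeks = inst$n_weeks)
    wl <- household_week_exposure(sw, sets, cfg_l)
    wa <- household_week_exposure(sw, sets, cfg_a)
    al <- annualize(wl, cfg_l)
    aa <- annualize(wa, cfg_a)

    # bounds
    expect_true(all(al$frequency >= 0 & al$frequency <= 1))
    expect_true(all(al$magnitude >= 0 & al$magnitude <= 1))
    # annual magnitude cannot exceed the largest weekly magnitude
    maxw <- tapply(wl$magnitude, wl$household_id, max)
    expect_true(all(al$magnitude <= maxw[al$household_id] + 1e-12))
    # dominance: largest >= average at every household-week
    merged <- merge(as.data.frame(wl), as.data.frame(wa),
                    by = c("household_id", "week_index"))
    expect_true(all(merged$magnitude.x >= merged$magnitude.y - 1e-12))
    # frequency is non-increasing in the threshold
    freqs <- sapply(c(0.02, 0.05, 0.10, 0.15), function(th) {
      cfg <- exposure_config(promo_threshold = th, n_weeks = inst$n_weeks)
      sum(annualize(wl, cfg)$frequency)
    })
    expect_true(all(diff(freqs) <= 1e-12))
  }
})

test_that("pipeline matches brute-force enumeration on small instances", {
  checked <- 0
  for (seed in 1:60) {
    inst <- random_instance(seed)
    got <- pipeline_exposure(inst)
    if (is.null(got)) next
    want <- oracle_exposure(inst$prices, inst$purchases, inst$stores,
                            inst$weights, inst$threshold, inst$aggregation,
                            inst$n_weeks)
    expect_equal(got$household_id, want$household_id)
    expect_equal(got$frequency, want$frequency, tolerance = 1e-12)
    expect_equal(got$magnitude, want$magnitude, tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gt(checked, 30)
})

test_that("sample-volume weights are purchase-volume proportions", {
  purch <- tibble::tibble(
    household_id = c("h1", "h1", "h2"),
    store_id = "s1", week_index = 1L,
    product_id = c("p1", "p2", "p1"),
    volume_oz = c(100, 300, 100)
  )
  w <- volume_weights(purch)
  expect_equal(w$weight[w$product_id == "p1"], 0.4) # 200 of 500 oz
  expect_equal(w$weight[w$product_id == "p2"], 0.6)
  expect_equal(sum(w$weight), 1)
  wu <- volume_weights(purch, scheme = "uniform")
  expect_equal(wu$weight, c(0.5, 0.5))
})
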