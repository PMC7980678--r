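small_cfg <- function(...) {
  generator_config(n_households = 80, n_stores = 6, n_products = 4, ...)
}

test_that("generation is deterministic in the seed", {
  a <- generate_scanner_data(small_cfg(seed = 31))
  b <- generate_scanner_data(small_cfg(seed = 31))
  for (nm in c("stores", "prices", "households", "purchases", "products")) {
    expect_identical(as.data.frame(a[[nm]]), as.data.frame(b[[nm]]), info = nm)
  }
  expect_identical(a$truth$annual, b$truth$annual)

  c <- generate_scanner_data(small_cfg(seed = 32))
  expect_false(identical(a$purchases$volume_oz, c$purchases$volume_oz))
})

test_that("no promotions means zero exposure everywhere", {
  ds <- generate_scanner_data(small_cfg(seed = 5, promo_prob = 0))
  expect_true(all(ds$truth$annual$frequency == 0))
  expect_true(all(ds$truth$annual$magnitude == 0))
  derived <- derive_exposure(ds, weights = ds$truth$weights)
  expect_true(all(derived$annual$frequency == 0))
  expect_true(all(derived$annual$magnitude == 0))
})

test_that("saturated constant-depth promotion yields full planted exposure", {
  ds <- generate_scanner_data(small_cfg(
    seed = 6, promo_prob = 1, promo_depth_mean = 0.10, promo_depth_sd = 0,
    stores_per_household = c(1, 1), price_missing_prob = 0
  ))
  expect_true(all(ds$truth$annual$frequency == 1))
  expect_equal(ds$truth$annual$magnitude, rep(0.10, nrow(ds$truth$annual)),
               tolerance = 1e-12)
})

test_that("planted truth is recovered exactly by the exposure pipeline", {
  ds <- generate_scanner_data(small_cfg(seed = 8))
  rep <- verify_truth(ds)
  expect_true(rep$ok)
  expect_lt(rep$max_weekly_deviation, 1e-9)

  # a perturbed price record is localised to its household-week
  bad <- ds
  covered_rows <- which(bad$prices$store_id %in% unique(
    household_store_sets(bad$purchases, bad$stores)$store_id
  ))
  i <- covered_rows[1]
  bad$prices$unit_price[i] <- bad$prices$unit_price[i] * 0.5
  err <- tryCatch(verify_truth(bad), error = function(e) conditionMessage(e))
  expect_match(err, "consistency failure")
  expect_match(err, sprintf("week %d", bad$prices$week_index[i]))
})

test_that("changing the threshold changes frequencies but not magnitudes", {
  ds <- generate_scanner_data(small_cfg(seed = 13))
  rep <- verify_truth(
    ds, config = exposure_config(promo_threshold = 0.10), strict = FALSE
  )
  expect_lt(rep$max_weekly_deviation, 1e-9)
  expect_lt(rep$max_magnitude_deviation, 1e-9)
  expect_gt(rep$max_frequency_deviation, 0)
})

test_that("store-week promotion rate matches promo_prob to Monte-Carlo error", {
  p <- 0.135
  ds <- generate_scanner_data(generator_config(
    n_households = 20, n_stores = 15, n_products = 8, seed = 17,
    promo_prob = p, price_missing_prob = 0
  ))
  joined <- dplyr::inner_join(ds$prices, ds$truth$planted_modal,
                              by = c("store_id", "product_id"))
  promoted <- joined$unit_price < joined$modal_unit_price * (1 - 1e-12)
  n <- length(promoted)
  expect_lt(abs(mean(promoted) - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("infeasible or invalid configurations are rejected", {
  expect_error(generator_config(n_stores = 3, stores_per_household = c(1, 5)),
               "infeasible")
  expect_error(generator_config(promo_prob = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(promo_depth_mean = 1.2), "\\(0, 1\\)")
  expect_error(generator_config(beta_freq_per10 = 0), "positive")
})

test_that("with a null planted effect the fitted estimates center on 1", {
  ests <- sapply(1:30, function(s) {
    cohort <- simulate_cohort(2000, beta_freq_per10 = 1.0, seed = 900 + s)
    fit_main(cohort, "frequency")$estimate$exp_estimate
  })
  expect_lt(abs(mean(ests) - 1), 0.02)
})

test_that("simulated cohorts match the intended exposure distribution", {
  cohort <- simulate_cohort(20000, seed = 77)
  expect_lt(abs(mean(cohort$frequency) - 0.444), 0.02)
  expect_lt(abs(sd(cohort$frequency) - 0.238), 0.02)
  expect_lt(abs(mean(cohort$magnitude) - 0.046), 0.006)
  expect_true(all(cohort$magnitude <= cohort$frequency))
  expect_true(all(cohort$annual_oz > 0))
  expect_equal(cohort$log_annual_oz, log(cohort$annual_oz))
})
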