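test_that("inclusion filter is inclusive at the boundary and monotone", {
  linkage <- tibble::tibble(
    household_id = c("a", "b", "c", "d"),
    total_oz = 100, covered_oz = c(80, 79, 100, 60),
    coverage = c(0.80, 0.79, 1.00, 0.60)
  )
  kept <- apply_inclusion(linkage, 0.80, quiet = TRUE)
  expect_setequal(kept$household_id, c("a", "c"))

  kept60 <- apply_inclusion(linkage, 0.60, quiet = TRUE)
  kept90 <- apply_inclusion(linkage, 0.90, quiet = TRUE)
  expect_true(all(kept90$household_id %in% kept60$household_id))
  expect_true(all(kept$household_id %in% kept60$household_id))

  expect_error(apply_inclusion(linkage, 0), "\\(0, 1\\]")
  expect_error(apply_inclusion(linkage, 1.2), "\\(0, 1\\]")
})

test_that("sample retention is reported in whole percent", {
  expect_equal(retention_percent(11299, 60169), 19)
  linkage <- tibble::tibble(
    household_id = as.character(1:10), total_oz = 100,
    covered_oz = c(rep(100, 2), rep(10, 8)), coverage = c(rep(1, 2), rep(0.1, 8))
  )
  kept <- apply_inclusion(linkage, 0.8, quiet = TRUE)
  expect_equal(attr(kept, "retention_percent"), 20)
})

test_that("per-capita outcome and serving conversions match hand arithmetic", {
  expect_equal(annual_per_capita(992, 2), 496)
  expect_equal(annual_per_capita(416, 1), 416)
  expect_equal(annual_per_capita(100, 4), 25)
  expect_error(annual_per_capita(100, 0), "size")
  expect_error(annual_per_capita(0, 2), "positive")

  expect_equal(oz_to_servings_per_week(496, digits = 1), 0.8)
  expect_equal(oz_to_servings_per_week(331), 0.53)
  expect_equal(oz_to_servings_per_week(670), 1.07)
  expect_error(oz_to_servings_per_week(-1), "nonnegative")
})

test_that("income per capita bins use midpoints and send boundaries up", {
  expect_equal(as.character(income_per_capita_bin("35k_49k", 3)), "le_15k")
  expect_equal(as.character(income_per_capita_bin("under_25k", 1)), "le_15k")
  expect_equal(as.character(income_per_capita_bin("100k_plus", 2)), "ge_50k")
  expect_equal(as.character(income_per_capita_bin("50k_69k", 2)), "15k_30k")
  expect_error(income_per_capita_bin("millionaire", 1), "not in midpoint map")
  expect_true(all(diff(income_midpoints()) > 0))
})

test_that("quartile partition is balanced, later-heavy and stable under ties", {
  q <- assign_quartiles(rnorm(11299))
  expect_equal(as.integer(attr(q, "sizes")), c(2824, 2825, 2825, 2825))
  expect_equal(as.integer(table(q)), c(2824, 2825, 2825, 2825))

  q8 <- assign_quartiles(c(5, 1, 7, 3, 8, 2, 6, 4))
  expect_equal(as.integer(table(q8)), c(2, 2, 2, 2))
  expect_equal(q8[order(c(5, 1, 7, 3, 8, 2, 6, 4))], rep(1:4, each = 2))

  ties <- assign_quartiles(rep(1, 4))
  expect_equal(as.integer(ties), 1:4) # stable input order
  expect_error(assign_quartiles(1:3), "at least 4")

  for (n in c(4, 5, 6, 7, 101, 1003)) {
    qq <- assign_quartiles(runif(n))
    sizes <- as.integer(table(qq))
    expect_equal(sum(sizes), n)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("cohort assembly computes outcome from all purchases", {
  tabs <- tiny_tables()
  annual <- tibble::tibble(
    household_id = c("h1", "h2"), frequency = c(0.5, 0.1),
    magnitude = c(0.05, 0.01)
  )
  included <- tibble::tibble(household_id = c("h1", "h2"))
  # quartiles need >= 4 households; pad with clones
  tabs$households <- dplyr::bind_rows(
    tabs$households,
    dplyr::mutate(tiny_household("h3", 1), income_category = "70k_99k"),
    tiny_household("h4", 4)
  )
  tabs$purchases <- dplyr::bind_rows(
    tabs$purchases,
    tibble::tibble(household_id = c("h3", "h4"), store_id = "s1",
                   week_index = 1L, product_id = "p1", volume_oz = c(50, 60))
  )
  annual <- dplyr::bind_rows(annual, tibble::tibble(
    household_id = c("h3", "h4"), frequency = 0.2, magnitude = 0.02
  ))
  included <- tibble::tibble(household_id = c("h1", "h2", "h3", "h4"))
  cohort <- build_cohort(tabs, annual, included)
  h1 <- cohort[cohort$household_id == "h1", ]
  # h1: 400 + 192 oz over size 2 -> 296 per capita
  expect_equal(h1$annual_oz, 296)
  expect_equal(h1$log_annual_oz, log(296))
  # h2's uncovered 100 oz still counts in the outcome: (300+100)/1
  expect_equal(cohort$annual_oz[cohort$household_id == "h2"], 400)
  expect_s3_class(cohort$income_per_capita_bin, "factor")
  expect_true(all(cohort$purchase_quartile %in% 1:4))
})

test_that("descriptive tables reproduce hand-computed summaries", {
  cohort <- simulate_cohort(120, seed = 5)
  tabs <- descriptive_tables(cohort)

  # percentages sum to 100 within each covariate block and quartile
  sums <- tabs$characteristics %>%
    dplyr::group_by(covariate, purchase_quartile) %>%
    dplyr::summarise(p = sum(percent), .groups = "drop")
  expect_true(all(abs(sums$p - 100) < 1e-9))

  overall <- tabs$purchase_summary[tabs$purchase_summary$group == "overall", ]
  expect_equal(overall$median, median(cohort$annual_oz))
  expect_equal(overall$mean, mean(cohort$annual_oz))
  expect_equal(overall$p25, unname(quantile(cohort$annual_oz, 0.25)))

  # degenerate outcome: IQR width zero
  flat <- dplyr::mutate(cohort, annual_oz = 500)
  t2 <- descriptive_tables(flat)$purchase_summary
  expect_equal(t2$p25[t2$group == "overall"], t2$p75[t2$group == "overall"])

  # exposure-by-covariate block has mean/sd per level
  race_rows <- tabs$exposure_by_covariate %>% dplyr::filter(covariate == "race")
  byhand <- tapply(cohort$frequency, as.character(cohort$race), mean)
  expect_equal(
    race_rows$frequency_mean[match(names(byhand), race_rows$level)],
    as.numeric(byhand)
  )
})

test_that("exposure summary reports the mean annual price ratio", {
  annual <- tibble::tibble(
    household_id = c("a", "b"), frequency = c(0.4, 0.48),
    magnitude = c(0.040, 0.052)
  )
  s <- summarize_exposure(annual)
  expect_equal(s$magnitude_mean, 0.046)
  expect_equal(s$mean_price_ratio, 1 - 0.046)
})
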