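test_that("percent change transforms exponentiated estimates", {
  expect_equal(percent_change(1.137), 13.7)
  expect_equal(percent_change(1.153), 15.3)
  expect_equal(percent_change(1.0), 0.0)
  expect_error(percent_change(0), "positive")
  # strictly increasing, and asymmetric on the log scale
  x <- seq(0.5, 2, by = 0.1)
  expect_true(all(diff(percent_change(x, digits = 10)) > 0))
  expect_false(isTRUE(all.equal(percent_change(1 / 1.2), -percent_change(1.2))))
})

test_that("main fit recovers a planted exposure effect", {
  cohort <- simulate_cohort(20000, beta_freq_per10 = 1.15, seed = 42)
  f <- fit_main(cohort, "frequency")
  est <- f$estimate
  # planted effect within ~3 standard errors on the log scale
  expect_lt(abs(est$beta - log(1.15)), 3 * est$se)
  expect_true(est$ci_low <= est$exp_estimate && est$exp_estimate <= est$ci_high)
  expect_gt(est$exp_estimate, 1.10)
  expect_lt(est$p_value, 1e-10)
  expect_equal(f$n, 20000)

  td <- tidy(f)
  expect_equal(td$estimate[1], est$exp_estimate)
  expect_equal(td$percent_change[1], percent_change(est$exp_estimate))
  g <- glance(f)
  expect_equal(g$n, 20000)
  expect_true(g$r.squared > 0 && g$r.squared < 1)
})

test_that("OLS slope is invariant to shifting the log outcome", {
  cohort <- simulate_cohort(3000, seed = 9)
  f1 <- fit_main(cohort, "magnitude")
  shifted <- dplyr::mutate(cohort, log_annual_oz = log_annual_oz + 3)
  f2 <- fit_main(shifted, "magnitude")
  expect_equal(f1$estimate$beta, f2$estimate$beta, tolerance = 1e-10)
})

test_that("structural no-head aliasing is tolerated, true collinearity is not", {
  cohort <- simulate_cohort(2000, seed = 3)
  expect_true(any(cohort$male_head_age == "no_head"))
  f <- fit_main(cohort, "frequency") # fits despite shared no-head class
  expect_s3_class(f, "promo_fit")

  dup <- dplyr::mutate(cohort, race_copy = race)
  expect_error(
    fit_main(dup, "frequency", covariates = c(promo_covariates(), "race_copy")),
    "singular design.*race_copy"
  )
})

test_that("stratum estimates agree with refits under releveled modifiers", {
  cohort <- simulate_cohort(4000, seed = 12)
  fi <- fit_interaction(cohort, "frequency", "race")
  expect_equal(nrow(fi$strata), 3)
  expect_true(all(fi$strata$ci_low <= fi$strata$exp_estimate &
                    fi$strata$exp_estimate <= fi$strata$ci_high))
  # releveling the modifier makes each stratum the reference in turn; its
  # exposure coefficient must equal the delta-method-combined estimate
  for (lev in c("black", "other")) {
    re <- dplyr::mutate(cohort, race = stats::relevel(race, ref = lev))
    fre <- fit_interaction(re, "frequency", "race")
    expect_equal(
      fi$strata$beta[fi$strata$level == lev],
      fre$strata$beta[fre$strata$level == lev],
      tolerance = 1e-8
    )
    expect_equal(
      fi$strata$se[fi$strata$level == lev],
      fre$strata$se[fre$strata$level == lev],
      tolerance = 1e-8
    )
  }
  # identical model, so the interaction F-test is invariant to releveling
  re2 <- fit_interaction(
    dplyr::mutate(cohort, race = stats::relevel(race, ref = "other")),
    "frequency", "race"
  )
  expect_equal(fi$interaction_p, re2$interaction_p, tolerance = 1e-10)
})

test_that("interaction test detects strongly different stratum slopes", {
  hits <- 0
  n_rep <- 20
  for (s in 1:n_rep) {
    cohort <- simulate_cohort(
      4000,
      beta_freq_per10 = c(white = 1.05, black = 1.30, other = 1.05),
      modifier = "race", seed = 5000 + s
    )
    fi <- fit_interaction(cohort, "frequency", "race")
    if (fi$interaction_p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.8)
})

test_that("null exposure CIs cover 1 at roughly the nominal rate", {
  covered <- 0
  n_rep <- 60
  for (s in 1:n_rep) {
    cohort <- simulate_cohort(3000, beta_freq_per10 = 1.0, seed = 7000 + s)
    f <- fit_main(cohort, "frequency")
    if (f$estimate$ci_low <= 1 && 1 <= f$estimate$ci_high) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.85)
})

test_that("empty modifier strata are rejected with the level named", {
  cohort <- simulate_cohort(500, seed = 2)
  cohort$race <- factor(as.character(cohort$race),
                        levels = c("white", "black", "other", "asian"))
  expect_error(fit_interaction(cohort, "frequency", "race"), "asian")
})
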