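#' Default adjustment covariates
#'
#' The covariate set of the adjusted purchase models: household size
#' (categorical), income per capita bin, age, education and occupation of the
#' male and female heads of household, presence of children, race, census
#' region and metropolitan status.
#'
#' Head age precedes head education and occupation deliberately: the three
#' variables of each sex share an identical "no head" class, so any full
#' dummy coding carries two structurally redundant columns per sex. With
#' this ordering the redundancy lands on the education/occupation "no head"
#' dummies, which [fit_main()] recognises as structural aliasing (their
#' effect is absorbed by the age variable) rather than a user error.
#'
#' @return Character vector of cohort column names.
#' @export
promo_covariates <- function() {
  c(
    "size_category", "income_per_capita_bin",
    "male_head_age", "female_head_age",
    "male_head_education", "female_head_education",
    "children_present", "race",
    "male_head_occupation", "female_head_occupation",
    "region", "metro"
  )
}

exposure_scale <- function(exposure) {
  # frequency enters x10 (per 10 percentage points), magnitude x100 (per 1
  # percentage point), so exponentiated coefficients read as percent changes
  # per the conventional increments.
  switch(exposure, frequency = 10, magnitude = 100)
}

#' Fit the adjusted log-linear purchase model
#'
#' Ordinary least squares of log annual per-capita purchase ounces on the
#' scaled exposure (promotion frequency multiplied by 10, or promotion
#' magnitude multiplied by 100) plus the dummy-coded adjustment covariates.
#' The exponentiated exposure coefficient is the multiplicative change in
#' annual per-capita purchase per 10-percentage-point increase in frequency
#' (or 1-point increase in magnitude), with a classical 95% confidence
#' interval.
#'
#' Aliased coefficients caused solely by the shared "no head" class (see
#' [promo_covariates()]) are tolerated; any other rank deficiency raises a
#' singular-design error naming the offending columns.
#'
#' @param cohort Cohort tibble from [build_cohort()] (complete cases on the
#'   model variables are required and enforced).
#' @param exposure `"frequency"` or `"magnitude"`.
#' @param covariates Character vector of adjustment columns (default
#'   [promo_covariates()]).
#' @param conf_level Confidence level (default 0.95).
#' @return A `promo_fit` object; see [tidy.promo_fit()], [glance.promo_fit()]
#'   and [autoplot.promo_fit()].
#' @export
fit_main <- function(cohort, exposure = c("frequency", "magnitude"),
                     covariates = promo_covariates(), conf_level = 0.95) {
  exposure <- match.arg(exposure)
  fit_promo_ols(cohort, exposure, covariates, modifier = NULL, conf_level)
}

#' Fit the subgroup interaction model
#'
#' A single model with exposure-by-modifier interaction terms on top of the
#' main-effects specification. Per-stratum exposure estimates are
#' reconstructed as `exp(beta_exposure + beta_interaction)` with delta-method
#' confidence intervals, and the interaction is tested with a Type-3
#' (extra-sum-of-squares) partial F-test of the full interaction block
#' against the main-effects model.
#'
#' @inheritParams fit_main
#' @param modifier One of `"income_per_capita_bin"`,
#'   `"female_head_education"`, `"race"` (any categorical cohort column with
#'   every level nonempty is accepted).
#' @return A `promo_fit` with a `strata` table and `interaction_p`.
#' @export
fit_interaction <- function(cohort, exposure = c("frequency", "magnitude"),
                            modifier, covariates = promo_covariates(),
                            conf_level = 0.95) {
  exposure <- match.arg(exposure)
  if (!modifier %in% names(cohort)) {
    abort(sprintf("modifier '%s' is not a cohort column", modifier))
  }
  fit_promo_ols(cohort, exposure, covariates, modifier = modifier, conf_level)
}

fit_promo_ols <- function(cohort, exposure, covariates, modifier, conf_level) {
  vars <- unique(c("log_annual_oz", exposure, covariates, modifier))
  missing_cols <- setdiff(vars, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing model column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dat <- cohort[vars]
  cc <- complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  if (any(dat[[exposure]] < 0)) abort("exposure must be nonnegative")
  if (any(!is.finite(dat$log_annual_oz))) {
    abort("log outcome must be finite (annual_oz must be positive)")
  }
  dat$.exposure_scaled <- dat[[exposure]] * exposure_scale(exposure)

  if (!is.null(modifier)) {
    if (!is.factor(dat[[modifier]])) dat[[modifier]] <- factor(dat[[modifier]])
    empty <- setdiff(levels(dat[[modifier]]), unique(as.character(dat[[modifier]])))
    if (length(empty) > 0) {
      abort(sprintf("modifier '%s' has empty level(s): %s", modifier,
                    paste(empty, collapse = ", ")))
    }
  }
  dat <- droplevels(dat)

  rhs <- c(".exposure_scaled", union(covariates, modifier))
  if (!is.null(modifier)) {
    rhs <- c(rhs, sprintf(".exposure_scaled:%s", modifier))
  }
  fml <- as.formula(paste("log_annual_oz ~", paste(rhs, collapse = " + ")))
  fit <- lm(fml, data = dat)
  check_singularity(fit)
  if (nrow(dat) <= fit$rank) {
    abort("cohort too small: n must exceed the number of model parameters")
  }

  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  df <- fit$df.residual
  tq <- qt(1 - (1 - conf_level) / 2, df)
  b <- cf[".exposure_scaled"]
  sb <- se[".exposure_scaled"]
  estimate <- tibble(
    exposure = exposure,
    beta = unname(b),
    se = unname(sb),
    exp_estimate = exp(unname(b)),
    ci_low = exp(unname(b - tq * sb)),
    ci_high = exp(unname(b + tq * sb)),
    p_value = 2 * pt(abs(unname(b / sb)), df, lower.tail = FALSE)
  )

  strata <- NULL
  interaction_p <- NA_real_
  if (!is.null(modifier)) {
    fml0 <- as.formula(paste(
      "log_annual_oz ~",
      paste(c(".exposure_scaled", union(covariates, modifier)), collapse = " + ")
    ))
    fit0 <- lm(fml0, data = dat)
    a <- anova(fit0, fit)
    interaction_p <- a$`Pr(>F)`[2]
    V <- vcov(fit)
    levs <- levels(dat[[modifier]])
    strata <- purrr::map_dfr(levs, function(l) {
      if (l == levs[1]) {
        est <- unname(b); v <- unname(sb)^2
      } else {
        term <- paste0(".exposure_scaled:", modifier, l)
        if (!term %in% rownames(V)) {
          abort(sprintf("interaction coefficient for level '%s' is not estimable", l))
        }
        est <- unname(b + cf[term])
        v <- V[".exposure_scaled", ".exposure_scaled"] + V[term, term] +
          2 * V[".exposure_scaled", term]
      }
      tibble(
        modifier = modifier, level = l,
        beta = est, se = sqrt(v),
        exp_estimate = exp(est),
        ci_low = exp(est - tq * sqrt(v)),
        ci_high = exp(est + tq * sqrt(v))
      )
    })
  }

  structure(
    list(
      fit = fit, exposure = exposure, scale = exposure_scale(exposure),
      modifier = modifier, estimate = estimate, strata = strata,
      interaction_p = interaction_p, n = nrow(dat), conf_level = conf_level
    ),
    class = "promo_fit"
  )
}

# Aliased coefficients are acceptable only when they are the structural
# "no head" redundancy shared by the head age/education/occupation variables.
check_singularity <- function(fit) {
  aliased <- names(coef(fit))[is.na(coef(fit))]
  if (length(aliased) == 0) return(invisible(TRUE))
  structural <- grepl("no_head$", aliased)
  if (!all(structural)) {
    abort(paste0(
      "singular design: the following column(s) are collinear with earlier terms: ",
      paste(aliased[!structural], collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Percent change implied by an exponentiated coefficient
#'
#' `100 * (exp_estimate - 1)`, rounded to one decimal: the percent change in
#' annual per-capita purchase per conventional exposure increment (10
#' percentage points of promotion frequency, or 1 percentage point of
#' promotion magnitude).
#'
#' @param exp_estimate Positive exponentiated estimate(s).
#' @param digits Decimals (default 1, the reporting convention).
#' @return Percent change(s).
#' @examples
#' percent_change(1.137) # 13.7
#' percent_change(1.153) # 15.3
#' @export
percent_change <- function(exp_estimate, digits = 1) {
  if (any(!is.finite(exp_estimate) | exp_estimate <= 0)) {
    abort("exp_estimate must be strictly positive")
  }
  round(100 * (exp_estimate - 1), digits)
}

#' @export
print.promo_fit <- function(x, ...) {
  cat(sprintf(
    "Log-linear purchase model (OLS), exposure: %s (x%d), n = %d\n",
    x$exposure, x$scale, x$n
  ))
  e <- x$estimate
  cat(sprintf(
    "  exp estimate %.3f (%d%% CI %.3f-%.3f), p = %.2g -> %+.1f%% per increment\n",
    e$exp_estimate, round(100 * x$conf_level), e$ci_low, e$ci_high,
    e$p_value, percent_change(e$exp_estimate)
  ))
  if (!is.null(x$strata)) {
    cat(sprintf("  interaction with %s: Type-3 P = %.4f\n",
                x$modifier, x$interaction_p))
    for (i in seq_len(nrow(x$strata))) {
      s <- x$strata[i, ]
      cat(sprintf("    %-14s %.3f (%.3f-%.3f)\n",
                  s$level, s$exp_estimate, s$ci_low, s$ci_high))
    }
  }
  invisible(x)
}

#' Tidy a fitted promotion model
#'
#' One row per reported estimate: the overall scaled-exposure term and, for
#' interaction fits, one row per modifier stratum. Estimates are on the
#' exponentiated (multiplicative) scale.
#'
#' @param x A `promo_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (exp scale), `conf.low`,
#'   `conf.high`, `p.value` (overall row only) and `percent_change`.
#' @method tidy promo_fit
#' @export
tidy.promo_fit <- function(x, ...) {
  out <- tibble(
    term = paste0(x$exposure, "_x", x$scale),
    estimate = x$estimate$exp_estimate,
    conf.low = x$estimate$ci_low,
    conf.high = x$estimate$ci_high,
    p.value = x$estimate$p_value
  )
  if (!is.null(x$strata)) {
    out <- bind_rows(out, tibble(
      term = paste0(x$modifier, ":", x$strata$level),
      estimate = x$strata$exp_estimate,
      conf.low = x$strata$ci_low,
      conf.high = x$strata$ci_high,
      p.value = NA_real_
    ))
  }
  mutate(out, percent_change = percent_change(.data$estimate))
}

#' Glance at a fitted promotion model
#'
#' @param x A `promo_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit-level summaries (`n`, `r.squared`,
#'   `sigma`, `exposure`, `interaction_p`).
#' @method glance promo_fit
#' @export
glance.promo_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = x$n,
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    exposure = x$exposure,
    modifier = x$modifier %||% NA_character_,
    interaction_p = x$interaction_p
  )
}
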