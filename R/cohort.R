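#' Apply the study inclusion filter
#'
#' Retains households that made at least `threshold` of their SSB purchase
#' volume (by ounces) at covered stores, so that the store price database is
#' representative of the retail environment where they actually shopped.
#' The comparison is inclusive: coverage exactly at the threshold is
#' retained. The retention percentage (rounded to whole percent, as reported)
#' is attached as attribute `"retention_percent"`.
#'
#' @param linkage A per-household coverage tibble from [linkage_report()].
#' @param threshold Minimum coverage fraction, in `(0, 1]` (default 0.80).
#' @param quiet Suppress the exclusion-count message.
#' @return The retained rows of `linkage`, with attributes `n_total`,
#'   `n_retained` and `retention_percent`.
#' @export
apply_inclusion <- function(linkage, threshold = 0.80, quiet = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    abort("coverage threshold must be a single number in (0, 1]")
  }
  retained <- filter(linkage, .data$coverage >= threshold)
  n_total <- nrow(linkage)
  n_ret <- nrow(retained)
  if (!quiet) {
    inform(sprintf(
      "inclusion filter (coverage >= %d%%): retained %d of %d households (%d%%), excluded %d",
      round(100 * threshold), n_ret, n_total,
      retention_percent(n_ret, n_total), n_total - n_ret
    ))
  }
  attr(retained, "n_total") <- n_total
  attr(retained, "n_retained") <- n_ret
  attr(retained, "retention_percent") <- retention_percent(n_ret, n_total)
  retained
}

#' Retention percentage of the inclusion filter
#'
#' `100 * n_retained / n_total`, rounded to the whole percent in which
#' sample-retention figures are reported.
#'
#' @param n_retained,n_total Household counts.
#' @return A percentage.
#' @examples
#' retention_percent(11299, 60169) # 19
#' @export
retention_percent <- function(n_retained, n_total) {
  if (any(n_total <= 0)) abort("n_total must be positive")
  round(100 * n_retained / n_total)
}

#' Annual per-capita purchase volume
#'
#' A household's total SSB purchase ounces over the year — covered and
#' uncovered stores alike, since the coverage filter conditions on where the
#' volume was bought but the outcome does not discard the remainder —
#' divided by household size.
#'
#' @param total_oz Total annual ounces (per household, vectorised).
#' @param size Household size, integer `>= 1`.
#' @return Per-capita ounces.
#' @examples
#' annual_per_capita(992, 2) # 496
#' annual_per_capita(416, 1) # one 12-oz 12-pack
#' @export
annual_per_capita <- function(total_oz, size) {
  if (any(size < 1)) abort("household size must be >= 1")
  if (any(total_oz <= 0)) abort("total_oz must be positive (only purchasers enter)")
  total_oz / size
}

#' Convert annual ounces to weekly 12-oz servings
#'
#' `annual_oz / (12 * 52)`, the standard serving basis for interpreting
#' annual purchase volumes.
#'
#' @param annual_oz Annual ounces, `>= 0`.
#' @param digits Decimals to report (default 2; use 1 where a single decimal
#'   is conventional).
#' @return Servings per week.
#' @examples
#' oz_to_servings_per_week(496, digits = 1) # 0.8
#' oz_to_servings_per_week(331) # 0.53
#' oz_to_servings_per_week(670) # 1.07
#' @export
oz_to_servings_per_week <- function(annual_oz, digits = 2) {
  if (any(annual_oz < 0)) abort("annual_oz must be nonnegative")
  round(annual_oz / (12 * 52), digits)
}

#' Income per capita bins
#'
#' Assigns each household to one of four ordered income-per-capita bins
#' (midpoint of its income bracket divided by household size). Values on a
#' bin boundary go to the higher bin.
#'
#' @param income_category Factor/character over the six income bracket levels.
#' @param size Household size.
#' @param midpoints Named midpoint vector, see [income_midpoints()].
#' @return A factor over `le_15k < 15k_30k < 30k_50k < ge_50k`.
#' @examples
#' income_per_capita_bin("35k_49k", 3) # 14000 -> le_15k
#' income_per_capita_bin("100k_plus", 2) # 50000 -> ge_50k
#' @export
income_per_capita_bin <- function(income_category, size, midpoints = income_midpoints()) {
  income_category <- as.character(income_category)
  unknown <- setdiff(unique(income_category), names(midpoints))
  if (length(unknown) > 0) {
    abort(paste0("income category not in midpoint map: ",
                 paste(unknown, collapse = ", ")))
  }
  ipc <- unname(midpoints[income_category]) / size
  cut(ipc, breaks = c(-Inf, 15000, 30000, 50000, Inf), right = FALSE,
      labels = promo_levels$income_per_capita_bin)
}

#' Rank-based quartile assignment
#'
#' Splits `n` values into four contiguous rank groups of as-equal-as-possible
#' size; when `n` is not divisible by 4 the extra members go to the later
#' quartiles, so earlier groups are never larger than later ones. Ties are
#' resolved by stable input order.
#'
#' @param values Numeric vector, `length >= 4`.
#' @return An integer vector of quartile labels 1..4, with the group sizes as
#'   attribute `"sizes"`.
#' @examples
#' table(assign_quartiles(rnorm(11299))) # 2824 2825 2825 2825
#' @export
assign_quartiles <- function(values) {
  n <- length(values)
  if (n < 4) abort("need at least 4 values to form quartiles")
  base <- n %/% 4
  rem <- n %% 4
  sizes <- base + c(rep(0L, 4L - rem), rep(1L, rem))
  ord <- order(values) # stable under ties
  q <- integer(n)
  q[ord] <- rep(1:4, times = sizes)
  attr(q, "sizes") <- sizes
  q
}

#' Assemble the analytic cohort
#'
#' Joins the retained households' outcome (annual per-capita ounces and its
#' log), annual exposure, and modelling covariates (including the derived
#' income-per-capita bin and the categorical household size) into one row
#' per household-year, with the purchase quartile labels used by the
#' descriptive tables.
#'
#' @param tables Validated table list.
#' @param annual_exposure Tibble `household_id`, `frequency`, `magnitude`
#'   (from [derive_exposure()]).
#' @param included Retained households from [apply_inclusion()] (or any
#'   tibble with a `household_id` column).
#' @return A cohort tibble, one row per included household.
#' @export
build_cohort <- function(tables, annual_exposure, included) {
  totals <- tables$purchases %>%
    group_by(.data$household_id) %>%
    summarise(total_oz = sum(.data$volume_oz), .groups = "drop")
  cohort <- tables$households %>%
    semi_join(included, by = "household_id") %>%
    inner_join(totals, by = "household_id") %>%
    inner_join(annual_exposure, by = "household_id") %>%
    mutate(
      annual_oz = annual_per_capita(.data$total_oz, .data$size),
      log_annual_oz = log(.data$annual_oz),
      income_per_capita_bin = income_per_capita_bin(.data$income_category, .data$size),
      size_category = size_category_of(.data$size)
    )
  mutate(cohort, purchase_quartile = assign_quartiles(cohort$annual_oz))
}

#' Descriptive cohort tables
#'
#' The three descriptive summaries of the study: household characteristics
#' by purchase quartile (counts and column percentages), the outcome
#' distribution overall, by beverage category and by exposure quartile
#' (mean/SD and median with 25th–75th percentiles), and mean/SD of the two
#' exposure variables by covariate level.
#'
#' @param cohort A cohort tibble from [build_cohort()].
#' @param purchases Optional purchase lines for the by-category outcome
#'   block; requires `products`.
#' @param products Optional product table with beverage categories.
#' @return A list of tibbles: `characteristics`, `purchase_summary`,
#'   `exposure_by_covariate`.
#' @export
descriptive_tables <- function(cohort, purchases = NULL, products = NULL) {
  covars <- c(
    "size_category", "income_category", "income_per_capita_bin",
    "male_head_age", "female_head_age", "male_head_education",
    "female_head_education", "male_head_occupation", "female_head_occupation",
    "children_present", "race", "hispanic", "region", "metro"
  )

  characteristics <- purrr::map_dfr(covars, function(v) {
    cohort %>%
      mutate(level = as.character(.data[[v]])) %>%
      count(.data$purchase_quartile, .data$level) %>%
      group_by(.data$purchase_quartile) %>%
      mutate(percent = 100 * .data$n / sum(.data$n)) %>%
      ungroup() %>%
      mutate(covariate = v, .before = 1)
  })

  num_summary <- function(x) {
    tibble(
      mean = mean(x), sd = sd(x), median = median(x),
      p25 = unname(quantile(x, 0.25)), p75 = unname(quantile(x, 0.75))
    )
  }

  overall <- dplyr::bind_cols(tibble(group = "overall", level = "all"),
                              num_summary(cohort$annual_oz))
  by_cat <- NULL
  if (!is.null(purchases) && !is.null(products)) {
    by_cat <- purchases %>%
      semi_join(cohort, by = "household_id") %>%
      inner_join(select(products, "product_id", "category"), by = "product_id") %>%
      group_by(.data$household_id, .data$category) %>%
      summarise(total_oz = sum(.data$volume_oz), .groups = "drop") %>%
      inner_join(select(cohort, "household_id", "size"), by = "household_id") %>%
      mutate(annual_oz = .data$total_oz / .data$size) %>%
      group_by(level = as.character(.data$category)) %>%
      summarise(num_summary(.data$annual_oz), .groups = "drop") %>%
      mutate(group = "beverage_category", .before = 1)
  }
  by_exposure <- purrr::map_dfr(c("frequency", "magnitude"), function(v) {
    cohort %>%
      mutate(q = assign_quartiles(.data[[v]])) %>%
      group_by(level = paste0("Q", .data$q)) %>%
      summarise(num_summary(.data$annual_oz), .groups = "drop") %>%
      mutate(group = paste0(v, "_quartile"), .before = 1)
  })
  purchase_summary <- bind_rows(overall, by_cat, by_exposure)

  exposure_by_covariate <- purrr::map_dfr(covars, function(v) {
    cohort %>%
      group_by(level = as.character(.data[[v]])) %>%
      summarise(
        n = n(),
        frequency_mean = mean(.data$frequency),
        frequency_sd = sd(.data$frequency),
        magnitude_mean = mean(.data$magnitude),
        magnitude_sd = sd(.data$magnitude),
        .groups = "drop"
      ) %>%
      mutate(covariate = v, .before = 1)
  })

  list(
    characteristics = characteristics,
    purchase_summary = purchase_summary,
    exposure_by_covariate = exposure_by_covariate
  )
}

#' Summarise annual exposure across households
#'
#' Sample means and SDs of the annual promotion frequency and magnitude,
#' plus the mean annual price ratio `1 - mean(magnitude)`: the average price
#' paid relative to the modal price (e.g. mean magnitude 0.046 means the
#' average annual price was 95.4% of the modal price).
#'
#' @param annual_exposure Tibble with `frequency` and `magnitude` columns.
#' @return A one-row tibble.
#' @export
summarize_exposure <- function(annual_exposure) {
  summarise(annual_exposure,
    n = n(),
    frequency_mean = mean(.data$frequency),
    frequency_sd = sd(.data$frequency),
    magnitude_mean = mean(.data$magnitude),
    magnitude_sd = sd(.data$magnitude),
    mean_price_ratio = 1 - mean(.data$magnitude)
  )
}
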