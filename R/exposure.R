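#' Exposure configuration
#'
#' Bundles the tunable choices that define promotion exposure: the discount
#' threshold at which a week counts as promoted, how discounts are aggregated
#' across the stores a household shops at, the product weighting scheme, and
#' the week calendar.
#'
#' @param promo_threshold Minimum fraction off the modal price for a week to
#'   count as promoted (default 0.05, i.e. a 5% discount; the comparison is
#'   inclusive). Must lie strictly between 0 and 1.
#' @param aggregation How a household's weekly exposure combines the
#'   store-week discounts across the stores it shopped at during the year:
#'   `"largest"` (the deepest discount on offer, the main definition) or
#'   `"average"` (the mean discount, the attenuated sensitivity definition).
#' @param weight_scheme Product weights used to standardise discounts within
#'   a store-week: `"sample_volume"` (proportional to total ounces purchased
#'   in the analytic sample) or `"uniform"`.
#' @param n_weeks Number of week bins in the calendar (default 52).
#' @return An object of class `exposure_config`.
#' @export
exposure_config <- function(promo_threshold = 0.05,
                            aggregation = c("largest", "average"),
                            weight_scheme = c("sample_volume", "uniform"),
                            n_weeks = 52) {
  if (!is.numeric(promo_threshold) || length(promo_threshold) != 1 ||
      promo_threshold <= 0 || promo_threshold >= 1) {
    abort("promo_threshold must be a single number strictly between 0 and 1")
  }
  structure(
    list(
      promo_threshold = promo_threshold,
      aggregation = match.arg(aggregation),
      weight_scheme = match.arg(weight_scheme),
      n_weeks = as.integer(n_weeks)
    ),
    class = "exposure_config"
  )
}

#' Modal (regular) prices per store and product
#'
#' The reference price against which promotions are measured is the modal
#' price: the most frequently observed weekly unit price of a product at a
#' store over the year. Frequency ties are broken towards the highest tied
#' price, because promotions deflect prices downward, so the regular price is
#' the upper mode. A single observation is its own mode.
#'
#' @param prices Validated weekly price tibble
#'   (`store_id`, `week_index`, `product_id`, `unit_price`).
#' @return A tibble `store_id`, `product_id`, `modal_unit_price`.
#' @examples
#' prices <- tibble::tibble(
#'   store_id = "s1", week_index = 1:5, product_id = "p1",
#'   unit_price = c(1, 1, 0.9, 1, 0.9)
#' )
#' compute_modal_prices(prices) # 1.0
#' @export
compute_modal_prices <- function(prices) {
  prices %>%
    count(.data$store_id, .data$product_id, .data$unit_price) %>%
    group_by(.data$store_id, .data$product_id) %>%
    filter(.data$n == max(.data$n)) %>%
    summarise(modal_unit_price = max(.data$unit_price), .groups = "drop")
}

#' Fractional discount of a weekly price from the modal price
#'
#' `max(0, (modal - price) / modal)`: the fraction off the regular price,
#' clamped at zero so that weeks priced above the modal price are "no
#' promotion", not a negative one.
#'
#' @param unit_price,modal_unit_price Strictly positive prices (vectorised).
#' @return Discount fractions in `[0, 1)`.
#' @examples
#' weekly_discount(0.95, 1.00) # 0.05
#' weekly_discount(1.10, 1.00) # 0
#' @export
weekly_discount <- function(unit_price, modal_unit_price) {
  if (any(!is.finite(unit_price) | unit_price <= 0) ||
      any(!is.finite(modal_unit_price) | modal_unit_price <= 0)) {
    abort("unit_price and modal_unit_price must be strictly positive")
  }
  pmax(0, (modal_unit_price - unit_price) / modal_unit_price)
}

#' Product volume weights
#'
#' Weights used to standardise promotion magnitude across stores so that a
#' deep discount on a marginal product does not count as much as one on a
#' high-volume product. Under `"sample_volume"` the weight of each product is
#' proportional to the total ounces of it purchased by the supplied (analytic
#' sample) purchase lines; under `"uniform"` all purchased products weigh
#' equally. Weights sum to 1.
#'
#' @param purchases Purchase lines of the analytic sample.
#' @param scheme `"sample_volume"` or `"uniform"`.
#' @return A tibble `product_id`, `weight`.
#' @export
volume_weights <- function(purchases, scheme = c("sample_volume", "uniform")) {
  scheme <- match.arg(scheme)
  w <- purchases %>%
    group_by(.data$product_id) %>%
    summarise(weight = sum(.data$volume_oz), .groups = "drop")
  if (scheme == "uniform") w$weight <- rep(1, nrow(w))
  mutate(w, weight = .data$weight / sum(.data$weight))
}

#' Volume-weighted promotion magnitude of each store-week
#'
#' For every store and week with at least one observed price, the weighted
#' mean of the product-level discounts from modal price, with the product
#' weights renormalised over the products actually observed in that
#' store-week. Store-weeks with no price observation are absent from the
#' result: a missing week carries no information and is not a zero discount.
#'
#' @param prices Validated weekly price tibble.
#' @param weights Product weight tibble from [volume_weights()]. Products
#'   present in `prices` but absent from `weights` get weight 0; if no
#'   observed product in a store-week has positive weight, the products
#'   observed there are weighted equally.
#' @param modal_prices Optional precomputed [compute_modal_prices()] output;
#'   recomputed from `prices` when `NULL`.
#' @return A tibble `store_id`, `week_index`, `magnitude`.
#' @export
store_week_magnitude <- function(prices, weights, modal_prices = NULL) {
  modal_prices <- modal_prices %||% compute_modal_prices(prices)
  prices %>%
    inner_join(modal_prices, by = c("store_id", "product_id")) %>%
    mutate(discount = weekly_discount(.data$unit_price, .data$modal_unit_price)) %>%
    left_join(weights, by = "product_id") %>%
    mutate(weight = dplyr::coalesce(.data$weight, 0)) %>%
    group_by(.data$store_id, .data$week_index) %>%
    summarise(
      magnitude = if (sum(.data$weight) > 0) {
        sum(.data$weight * .data$discount) / sum(.data$weight)
      } else {
        mean(.data$discount)
      },
      .groups = "drop"
    )
}

#' Household store sets
#'
#' The covered stores at which each household purchased SSBs at any point in
#' the year. Exposure is defined over this year-long store set, not the
#' stores visited in a particular week.
#'
#' @param purchases Validated purchase lines.
#' @param stores Validated store table (defines coverage).
#' @return A tibble `household_id`, `store_id` (distinct pairs).
#' @export
household_store_sets <- function(purchases, stores) {
  purchases %>%
    filter(.data$store_id %in% unique(stores$store_id)) %>%
    distinct(.data$household_id, .data$store_id)
}

#' Weekly promotion exposure per household
#'
#' Combines the store-week magnitudes across each household's store set into
#' one value per week: the largest discount on offer among those stores
#' (main definition) or the average (sensitivity definition). Weeks in which
#' no store in the set has an observed magnitude score 0, keeping every
#' household's weekly series at full calendar length.
#'
#' @param store_week Output of [store_week_magnitude()].
#' @param store_sets Output of [household_store_sets()]; every household must
#'   have at least one covered store.
#' @param config An [exposure_config()].
#' @return A tibble `household_id`, `week_index`, `magnitude` with exactly
#'   `config$n_weeks` rows per household.
#' @export
household_week_exposure <- function(store_week, store_sets, config = exposure_config()) {
  if (nrow(store_sets) == 0) {
    abort("store_sets is empty: households without a covered store cannot be scored")
  }
  agg <- if (config$aggregation == "largest") max else mean
  observed <- store_sets %>%
    inner_join(store_week, by = "store_id", relationship = "many-to-many") %>%
    group_by(.data$household_id, .data$week_index) %>%
    summarise(magnitude = agg(.data$magnitude), .groups = "drop")
  grid <- tidyr::expand_grid(
    household_id = unique(store_sets$household_id),
    week_index = seq_len(config$n_weeks)
  )
  grid %>%
    left_join(observed, by = c("household_id", "week_index")) %>%
    mutate(magnitude = dplyr::coalesce(.data$magnitude, 0))
}

#' Annualise weekly exposures
#'
#' Reduces each household's weekly promotion magnitudes to the two annual
#' exposure variables: `frequency`, the fraction of the year's weeks whose
#' magnitude reaches the promotion threshold (inclusive), and `magnitude`,
#' the arithmetic mean of all weekly magnitudes including sub-threshold
#' weeks. Both denominators are the full calendar length.
#'
#' @param weekly Output of [household_week_exposure()]; every household must
#'   contribute exactly `config$n_weeks` weeks.
#' @param config An [exposure_config()].
#' @return A tibble `household_id`, `frequency`, `magnitude`.
#' @examples
#' weekly <- tibble::tibble(
#'   household_id = "h1", week_index = 1:52,
#'   magnitude = c(rep(0.06, 23), rep(0, 29))
#' )
#' annualize(weekly) # frequency 23/52, magnitude ~0.0265
#' @export
annualize <- function(weekly, config = exposure_config()) {
  counts <- count(weekly, .data$household_id)
  if (any(counts$n != config$n_weeks)) {
    bad <- counts$household_id[counts$n != config$n_weeks][1]
    abort(sprintf(
      "household %s has %d weekly values; expected exactly %d",
      bad, counts$n[counts$household_id == bad], config$n_weeks
    ))
  }
  weekly %>%
    group_by(.data$household_id) %>%
    summarise(
      frequency = sum(.data$magnitude >= config$promo_threshold) / config$n_weeks,
      magnitude = mean(.data$magnitude),
      .groups = "drop"
    )
}

#' Derive annual promotion exposure for every covered household
#'
#' Runs the full exposure pipeline: modal prices, product volume weights,
#' store-week magnitudes, household-week aggregation over each household's
#' store set, and annualisation.
#'
#' @param tables Validated table list (see [read_tables()]).
#' @param config An [exposure_config()].
#' @param weights Optional precomputed product weight tibble (overrides
#'   `config$weight_scheme`); used to hold weights fixed across sensitivity
#'   cells or to score against externally supplied weights.
#' @param sample_ids Optional household ids defining the analytic sample for
#'   the `"sample_volume"` weights; defaults to all purchasing households.
#' @return A list with `annual` (`household_id`, `frequency`, `magnitude`),
#'   `weekly`, `store_week`, `modal_prices` and `weights`.
#' @export
derive_exposure <- function(tables, config = exposure_config(), weights = NULL,
                            sample_ids = NULL) {
  modal <- compute_modal_prices(tables$prices)
  if (is.null(weights)) {
    pw <- tables$purchases
    if (!is.null(sample_ids)) pw <- filter(pw, .data$household_id %in% sample_ids)
    weights <- volume_weights(pw, scheme = config$weight_scheme)
  }
  store_week <- store_week_magnitude(tables$prices, weights, modal_prices = modal)
  store_sets <- household_store_sets(tables$purchases, tables$stores)
  weekly <- household_week_exposure(store_week, store_sets, config)
  annual <- annualize(weekly, config)
  list(annual = annual, weekly = weekly, store_week = store_week,
       modal_prices = modal, weights = weights)
}
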