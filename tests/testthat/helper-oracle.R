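# Independent brute-force oracle for the exposure pipeline: plain base-R
# loops over every (store, product, week) triple, no shared code with the
# package internals. Used to cross-check the dplyr pipeline on small random
# instances.

oracle_modal <- function(prices) {
  out <- list()
  for (s in unique(prices$store_id)) {
    for (p in unique(prices$product_id[prices$store_id == s])) {
      v <- prices$unit_price[prices$store_id == s & prices$product_id == p]
      tab <- table(v)
      modes <- as.numeric(names(tab)[tab == max(tab)])
      out[[paste(s, p)]] <- list(store_id = s, product_id = p,
                                 modal = max(modes))
    }
  }
  out
}

# Annual frequency/magnitude per household by full enumeration.
oracle_exposure <- function(prices, purchases, stores, weights,
                            threshold = 0.05, aggregation = "largest",
                            n_weeks = 52) {
  modal <- oracle_modal(prices)
  wt <- setNames(weights$weight, weights$product_id)
  covered <- unique(stores$store_id)
  hh_ids <- sort(unique(purchases$household_id[purchases$store_id %in% covered]))

  res <- data.frame(household_id = character(0), frequency = numeric(0),
                    magnitude = numeric(0))
  for (h in hh_ids) {
    set_h <- unique(purchases$store_id[purchases$household_id == h &
                                         purchases$store_id %in% covered])
    weekly <- numeric(n_weeks)
    for (w in seq_len(n_weeks)) {
      store_mags <- c()
      for (s in set_h) {
        rows <- prices$store_id == s & prices$week_index == w
        if (!any(rows)) next
        prods <- prices$product_id[rows]
        discounts <- numeric(0)
        wvec <- numeric(0)
        for (p in prods) {
          m <- modal[[paste(s, p)]]$modal
          price <- prices$unit_price[rows & prices$product_id == p]
          discounts <- c(discounts, max(0, (m - price) / m))
          wvec <- c(wvec, if (p %in% names(wt)) wt[[p]] else 0)
        }
        mag <- if (sum(wvec) > 0) {
          sum(wvec * discounts) / sum(wvec)
        } else {
          mean(discounts)
        }
        store_mags <- c(store_mags, mag)
      }
      weekly[w] <- if (length(store_mags) == 0) {
        0
      } else if (aggregation == "largest") {
        max(store_mags)
      } else {
        mean(store_mags)
      }
    }
    res <- rbind(res, data.frame(
      household_id = h,
      frequency = sum(weekly >= threshold) / n_weeks,
      magnitude = mean(weekly)
    ))
  }
  res
}

# Random tiny instance: <= 3 stores, <= 3 products, <= 6 weeks, discrete
# price levels so that modal ties occur, occasional missing store-weeks and
# uncovered purchases.
random_instance <- function(seed) {
  set.seed(seed)
  n_stores <- sample(1:3, 1)
  n_products <- sample(1:3, 1)
  n_weeks <- sample(2:6, 1)
  n_households <- sample(1:4, 1)
  stores <- tibble::tibble(
    store_id = sprintf("s%d", seq_len(n_stores)),
    retailer_code = sprintf("r%d", seq_len(n_stores)),
    channel = "food", metro = "metropolitan"
  )
  grid <- expand.grid(
    store_id = stores$store_id,
    product_id = sprintf("p%d", seq_len(n_products)),
    week_index = seq_len(n_weeks), stringsAsFactors = FALSE
  )
  keep <- runif(nrow(grid)) < 0.85
  if (!any(keep)) keep[1] <- TRUE
  prices <- grid[keep, ]
  prices$unit_price <- sample(c(0.8, 0.9, 1.0, 1.1), nrow(prices), replace = TRUE)
  purchases <- tibble::tibble(
    household_id = sprintf("h%d", sample(seq_len(n_households),
                                         n_households * 2, replace = TRUE)),
    store_id = sample(c(stores$store_id, "u1"), n_households * 2,
                      replace = TRUE, prob = c(rep(0.9 / n_stores, n_stores), 0.1)),
    week_index = sample(seq_len(n_weeks), n_households * 2, replace = TRUE),
    product_id = sample(sprintf("p%d", seq_len(n_products)),
                        n_households * 2, replace = TRUE),
    volume_oz = round(runif(n_households * 2, 10, 400), 1)
  )
  w <- rgamma(n_products, 1)
  weights <- tibble::tibble(
    product_id = sprintf("p%d", seq_len(n_products)),
    weight = w / sum(w)
  )
  threshold <- sample(c(0.02, 0.05, 0.10, 0.15), 1)
  aggregation <- sample(c("largest", "average"), 1)
  list(
    stores = stores, prices = tibble::as_tibble(prices),
    purchases = purchases, weights = weights,
    threshold = threshold, aggregation = aggregation, n_weeks = n_weeks
  )
}

# Pipeline counterpart over the same instance, via the package functions.
pipeline_exposure <- function(inst) {
  cfg <- exposure_config(
    promo_threshold = inst$threshold, aggregation = inst$aggregation,
    n_weeks = inst$n_weeks
  )
  sw <- store_week_magnitude(inst$prices, inst$weights)
  sets <- household_store_sets(inst$purchases, inst$stores)
  if (nrow(sets) == 0) return(NULL)
  weekly <- household_week_exposure(sw, sets, cfg)
  out <- annualize(weekly, cfg)
  out[order(out$household_id), ]
}
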