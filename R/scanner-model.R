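#' Read and validate the scanner and panel input tables
#'
#' Reads the four study tables (plus the optional product table) from CSV and
#' validates them: schema (exact column names), closed category sets, strictly
#' positive prices and volumes, week indexes inside the calendar, and
#' uniqueness of the weekly price series. Purchases made at stores absent from
#' the store table are legitimate ("uncovered" stores outside the retailer
#' price database) and are retained; they matter only for the coverage filter.
#'
#' @param data_dir Directory containing `stores.csv`, `prices.csv`,
#'   `households.csv`, `purchases.csv` and optionally `products.csv`.
#' @param n_weeks Number of week bins in the calendar year (default 52; the
#'   year is represented as 52 seven-day bins, the final odd days folding into
#'   the last bin).
#' @param quiet Suppress the per-table row-count messages.
#'
#' @return A named list of validated tibbles: `stores`, `prices`,
#'   `households`, `purchases`, and `products` (`NULL` when no product file
#'   is present).
#' @seealso [write_tables()], [linkage_report()]
#' @export
read_tables <- function(data_dir, n_weeks = 52, quiet = FALSE) {
  paths <- file.path(data_dir, c(
    stores = "stores.csv", prices = "prices.csv",
    households = "households.csv", purchases = "purchases.csv"
  ))
  names(paths) <- c("stores", "prices", "households", "purchases")
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("Input file(s) not found: ", paste(missing, collapse = ", ")))
  }
  # base parser: correctly rounded doubles, so write/read round trips exactly
  read1 <- function(path) {
    as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  tables <- lapply(paths, read1)
  products_path <- file.path(data_dir, "products.csv")
  tables$products <- if (file.exists(products_path)) read1(products_path) else NULL
  tables <- validate_tables(tables, n_weeks = n_weeks)
  if (!quiet) {
    for (nm in names(tables)) {
      if (!is.null(tables[[nm]])) {
        inform(sprintf("read %s: %d rows", nm, nrow(tables[[nm]])))
      }
    }
  }
  tables
}

#' Write the scanner and panel tables to CSV
#'
#' Inverse of [read_tables()]: writes each table in the documented CSV
#' dialect (UTF-8, header row, comma-delimited). Doubles are written with
#' shortest round-trip precision so a write/read cycle reproduces every field
#' exactly.
#'
#' @param tables Named list with `stores`, `prices`, `households`,
#'   `purchases` and optionally `products` (as returned by [read_tables()]
#'   or [generate_scanner_data()]).
#' @param data_dir Output directory, created if needed.
#' @return `data_dir`, invisibly.
#' @export
write_tables <- function(tables, data_dir) {
  dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("stores", "prices", "households", "purchases", "products")) {
    tab <- tables[[nm]]
    if (is.null(tab)) next
    out <- tab
    out[] <- lapply(out, function(col) if (is.factor(col)) as.character(col) else col)
    readr::write_csv(out, file.path(data_dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  invisible(data_dir)
}

# ---- validation ------------------------------------------------------------

require_columns <- function(tab, cols, table) {
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0) {
    abort(sprintf(
      "Schema error in table '%s': missing column(s) %s", table,
      paste0("'", missing, "'", collapse = ", ")
    ))
  }
}

check_positive <- function(x, field, table) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Value error in table '%s': column '%s' must be strictly positive; first offending row: %d",
      table, field, bad[1]
    ))
  }
}

check_week <- function(x, n_weeks, table) {
  bad <- which(is.na(x) | x < 1 | x > n_weeks | x != floor(x))
  if (length(bad) > 0) {
    abort(sprintf(
      "Value error in table '%s': week_index must be an integer in 1..%d; first offending row: %d",
      table, n_weeks, bad[1]
    ))
  }
}

#' Validate in-memory study tables
#'
#' Applies the same checks as [read_tables()] to tables already in memory,
#' returning them with identifier columns as character and categorical
#' columns as factors over the closed level sets.
#'
#' @inheritParams write_tables
#' @inheritParams read_tables
#' @return The validated list of tibbles.
#' @export
validate_tables <- function(tables, n_weeks = 52) {
  stores <- as_tibble(tables$stores)
  require_columns(stores, c("store_id", "retailer_code", "channel", "metro"), "stores")
  stores <- mutate(stores,
    store_id = as.character(.data$store_id),
    retailer_code = as.character(.data$retailer_code),
    channel = as_enum(.data$channel, promo_levels$channel, "channel", "stores"),
    metro = as_enum(.data$metro, promo_levels$metro, "metro", "stores")
  )
  if (anyDuplicated(stores$store_id) > 0) {
    abort("Integrity error in table 'stores': duplicate store_id")
  }

  prices <- as_tibble(tables$prices)
  require_columns(prices, c("store_id", "week_index", "product_id", "unit_price"), "prices")
  prices <- mutate(prices,
    store_id = as.character(.data$store_id),
    product_id = as.character(.data$product_id),
    week_index = as.integer(.data$week_index)
  )
  check_week(prices$week_index, n_weeks, "prices")
  check_positive(prices$unit_price, "unit_price", "prices")
  dup <- duplicated(prices[c("store_id", "week_index", "product_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf(
      "Integrity error in table 'prices': duplicate (store_id, week_index, product_id) at row %d (%s, week %d, %s)",
      i, prices$store_id[i], prices$week_index[i], prices$product_id[i]
    ))
  }

  households <- as_tibble(tables$households)
  hh_cols <- c(
    "household_id", "size", "income_category", "male_head_age",
    "female_head_age", "male_head_education", "female_head_education",
    "male_head_occupation", "female_head_occupation", "children_present",
    "race", "hispanic", "region", "metro"
  )
  require_columns(households, hh_cols, "households")
  households <- mutate(households,
    household_id = as.character(.data$household_id),
    size = as.integer(.data$size),
    income_category = as_enum(.data$income_category, promo_levels$income_category,
                              "income_category", "households"),
    male_head_age = as_enum(.data$male_head_age, promo_levels$head_age,
                            "male_head_age", "households"),
    female_head_age = as_enum(.data$female_head_age, promo_levels$head_age,
                              "female_head_age", "households"),
    male_head_education = as_enum(.data$male_head_education, promo_levels$head_education,
                                  "male_head_education", "households"),
    female_head_education = as_enum(.data$female_head_education, promo_levels$head_education,
                                    "female_head_education", "households"),
    male_head_occupation = as_enum(.data$male_head_occupation, promo_levels$head_occupation,
                                   "male_head_occupation", "households"),
    female_head_occupation = as_enum(.data$female_head_occupation, promo_levels$head_occupation,
                                     "female_head_occupation", "households"),
    children_present = as.logical(.data$children_present),
    race = as_enum(.data$race, promo_levels$race, "race", "households"),
    hispanic = as.logical(.data$hispanic),
    region = as_enum(.data$region, promo_levels$region, "region", "households"),
    metro = as_enum(.data$metro, promo_levels$metro, "metro", "households")
  )
  if (anyDuplicated(households$household_id) > 0) {
    abort("Integrity error in table 'households': duplicate household_id")
  }
  if (any(is.na(households$size) | households$size < 1)) {
    abort("Value error in table 'households': size must be an integer >= 1")
  }
  check_head_consistency(households, "male")
  check_head_consistency(households, "female")

  purchases <- as_tibble(tables$purchases)
  require_columns(purchases, c("household_id", "store_id", "week_index",
                               "product_id", "volume_oz"), "purchases")
  purchases <- mutate(purchases,
    household_id = as.character(.data$household_id),
    store_id = as.character(.data$store_id),
    product_id = as.character(.data$product_id),
    week_index = as.integer(.data$week_index)
  )
  check_week(purchases$week_index, n_weeks, "purchases")
  check_positive(purchases$volume_oz, "volume_oz", "purchases")

  products <- tables$products
  if (!is.null(products)) {
    products <- as_tibble(products)
    require_columns(products, c("product_id", "category", "package_oz"), "products")
    products <- mutate(products,
      product_id = as.character(.data$product_id),
      category = as_enum(.data$category, promo_levels$category, "category", "products")
    )
    check_positive(products$package_oz, "package_oz", "products")
    if (anyDuplicated(products$product_id) > 0) {
      abort("Integrity error in table 'products': duplicate product_id")
    }
  }

  list(stores = stores, prices = prices, households = households,
       purchases = purchases, products = products)
}

# A household head that is recorded absent in one field must be absent in all
# three fields for that sex.
check_head_consistency <- function(households, sex) {
  fields <- paste0(sex, c("_head_age", "_head_education", "_head_occupation"))
  absent <- sapply(fields, function(f) households[[f]] == "no_head")
  inconsistent <- which(rowSums(absent) %in% c(1, 2))
  if (length(inconsistent) > 0) {
    abort(sprintf(
      "Integrity error in table 'households': inconsistent %s-head absence for household_id %s",
      sex, households$household_id[inconsistent[1]]
    ))
  }
}

#' Per-household linkage between panel purchases and the store price database
#'
#' Summarises, for every purchasing household, how much of its purchase
#' volume was made at "covered" stores (stores present in the price table)
#' versus uncovered outlets. The resulting `coverage` fraction drives the
#' study inclusion filter ([apply_inclusion()]): the exposure variables can
#' only be constructed from stores whose weekly prices are observed.
#'
#' @param purchases Validated purchase-line tibble.
#' @param stores Validated store tibble (defines coverage).
#' @return A tibble with one row per household: `household_id`, `total_oz`,
#'   `covered_oz`, `coverage` (in `[0, 1]`).
#' @examples
#' stores <- tibble::tibble(
#'   store_id = "s1", retailer_code = "r1",
#'   channel = "food", metro = "metropolitan"
#' )
#' purchases <- tibble::tibble(
#'   household_id = "h1", store_id = c("s1", "u9"),
#'   week_index = 1L, product_id = "p1", volume_oz = c(80, 20)
#' )
#' linkage_report(purchases, stores) # coverage 0.8
#' @export
linkage_report <- function(purchases, stores) {
  covered_ids <- unique(stores$store_id)
  purchases %>%
    group_by(.data$household_id) %>%
    summarise(
      total_oz = sum(.data$volume_oz),
      covered_oz = sum(.data$volume_oz[.data$store_id %in% covered_ids]),
      .groups = "drop"
    ) %>%
    filter(.data$total_oz > 0) %>%
    mutate(coverage = .data$covered_oz / .data$total_oz)
}
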