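# Small hand-built tables shared by the unit tests. All fixtures are built
# in code; nothing is read from disk except in round-trip tests that write
# to a tempdir first.

tiny_stores <- function(n = 2) {
  tibble::tibble(
    store_id = sprintf("s%d", seq_len(n)),
    retailer_code = sprintf("r%d", seq_len(n)),
    channel = rep(c("food", "drug", "mass"), length.out = n),
    metro = rep(c("metropolitan", "urban_rural"), length.out = n)
  )
}

tiny_products <- function(n = 3) {
  tibble::tibble(
    product_id = sprintf("p%d", seq_len(n)),
    category = rep(c("carbonated_soft_drink", "fruit_drink"), length.out = n),
    package_oz = rep(c(416, 195, 144), length.out = n)
  )
}

tiny_household <- function(id = "h1", size = 2, income = "50k_69k") {
  tibble::tibble(
    household_id = id, size = size, income_category = income,
    male_head_age = "35_54", female_head_age = "35_54",
    male_head_education = "college_grad", female_head_education = "some_college",
    male_head_occupation = "white_collar", female_head_occupation = "white_collar",
    children_present = TRUE, race = "white", hispanic = FALSE,
    region = "pacific", metro = "metropolitan"
  )
}

# A complete valid table set: 2 stores, 3 products, full 52-week price grid
# with one promoted week, 2 households.
tiny_tables <- function() {
  stores <- tiny_stores(2)
  products <- tiny_products(3)
  grid <- expand.grid(
    store_id = stores$store_id, product_id = products$product_id,
    week_index = 1:52, stringsAsFactors = FALSE
  )
  grid$unit_price <- 0.06
  grid$unit_price[grid$week_index == 10 & grid$store_id == "s1"] <- 0.05
  households <- dplyr::bind_rows(
    tiny_household("h1", 2),
    tiny_household("h2", 1, income = "under_25k")
  )
  purchases <- tibble::tibble(
    household_id = c("h1", "h1", "h2", "h2"),
    store_id = c("s1", "s2", "s1", "u99"),
    week_index = c(10L, 20L, 5L, 6L),
    product_id = c("p1", "p2", "p1", "p3"),
    volume_oz = c(400, 192, 300, 100)
  )
  validate_tables(list(
    stores = stores,
    prices = grid[c("store_id", "week_index", "product_id", "unit_price")],
    households = households, purchases = purchases, products = products
  ))
}

# Weekly exposure vector -> tibble in the shape annualize() expects.
weekly_tbl <- function(magnitudes, id = "h1") {
  tibble::tibble(
    household_id = id,
    week_index = seq_along(magnitudes),
    magnitude = magnitudes
  )
}
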