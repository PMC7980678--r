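# Closed category sets shared by the readers, the generator and the models.
# Level order matters: the first level of each covariate is the dummy-coding
# reference in the regressions, and ordered sets (income, age, education)
# follow increasing order with the "absent head" level last.

promo_levels <- list(
  channel = c("food", "drug", "mass"),
  metro = c("metropolitan", "urban_rural"),
  category = c("carbonated_soft_drink", "fruit_drink"),
  income_category = c(
    "under_25k", "25k_34k", "35k_49k", "50k_69k", "70k_99k", "100k_plus"
  ),
  head_age = c("under_35", "35_54", "55_plus", "no_head"),
  head_education = c("hs_or_less", "some_college", "college_grad", "no_head"),
  head_occupation = c("white_collar", "blue_collar", "other", "no_head"),
  race = c("white", "black", "other"),
  region = c(
    "new_england", "middle_atlantic", "east_north_central",
    "west_north_central", "south_atlantic", "east_south_central",
    "west_south_central", "mountain", "pacific"
  ),
  income_per_capita_bin = c("le_15k", "15k_30k", "30k_50k", "ge_50k"),
  size_category = c("1", "2", "3_4", "5_plus")
)

#' Midpoints of the household income brackets
#'
#' Dollar midpoints assigned to the six reported household income brackets,
#' used to derive income per capita (midpoint divided by household size).
#' The open top bracket is top-coded at its floor of $100,000.
#'
#' @return A named numeric vector, one strictly increasing midpoint per
#'   income bracket level.
#' @examples
#' income_midpoints()
#' @export
income_midpoints <- function() {
  c(
    under_25k = 12500, `25k_34k` = 29500, `35k_49k` = 42000,
    `50k_69k` = 59500, `70k_99k` = 84500, `100k_plus` = 100000
  )
}

# Coerce a character column to a factor over a closed level set; unknown
# values are a validation error, not silent NAs.
as_enum <- function(x, levels, field, table) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid value(s) %s in column '%s' of table '%s'; allowed: %s",
      paste0("'", bad, "'", collapse = ", "), field, table,
      paste(levels, collapse = ", ")
    ))
  }
  factor(x, levels = levels)
}

# Household size collapsed to the reported category set.
size_category_of <- function(size) {
  factor(
    dplyr::case_when(
      size == 1 ~ "1",
      size == 2 ~ "2",
      size <= 4 ~ "3_4",
      TRUE ~ "5_plus"
    ),
    levels = promo_levels$size_category
  )
}
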