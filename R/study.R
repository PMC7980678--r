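#' Manifest of the full study grid
#'
#' Defines the sensitivity grid: promotion thresholds crossed with
#' store-aggregation modes for the exposure definition, and coverage
#' thresholds for the inclusion filter. The main-analysis cell — threshold
#' 0.05, largest-discount aggregation, coverage 0.80 — is always present and
#' is flagged in the results.
#'
#' @param thresholds Promotion thresholds (default 0.02, 0.05, 0.10, 0.15).
#' @param aggregations Store aggregation modes (default both `largest` and
#'   `average`).
#' @param coverages Coverage thresholds for inclusion (default 0.60, 0.70,
#'   0.80, 0.90).
#' @param exposures Exposure variables to fit (default both).
#' @param modifiers Modifiers for the interaction fits of the main cell.
#' @return A `run_manifest` object.
#' @export
run_manifest <- function(thresholds = c(0.02, 0.05, 0.10, 0.15),
                         aggregations = c("largest", "average"),
                         coverages = c(0.60, 0.70, 0.80, 0.90),
                         exposures = c("frequency", "magnitude"),
                         modifiers = c("income_per_capita_bin",
                                       "female_head_education", "race")) {
  thresholds <- sort(unique(c(thresholds, 0.05)))
  coverages <- sort(unique(c(coverages, 0.80)))
  aggregations <- unique(c(aggregations, "largest"))
  structure(
    list(thresholds = thresholds, aggregations = aggregations,
         coverages = coverages, exposures = exposures, modifiers = modifiers),
    class = "run_manifest"
  )
}

is_main_cell <- function(threshold, aggregation, coverage) {
  threshold == 0.05 & aggregation == "largest" & coverage == 0.80
}

#' Run the end-to-end study over the sensitivity grid
#'
#' For every grid cell (promotion threshold x aggregation mode x coverage
#' threshold) this derives the cohort and fits the adjusted log-linear model
#' for each exposure variable. Exposure tables are derived once per
#' (threshold, aggregation) pair and reused across coverage cells, with
#' product volume weights computed once from the main-analysis sample
#' (coverage 0.80). Interaction fits and the descriptive tables are produced
#' for the main cell only. A failing cell is recorded and skipped; it does
#' not abort the grid.
#'
#' @param tables Validated table list (see [read_tables()] or
#'   [generate_scanner_data()]).
#' @param manifest A [run_manifest()].
#' @param quiet Suppress progress messages.
#' @return A `promo_bundle`: list with `fits` (one row per cell and
#'   exposure), `interactions`, `tables` (descriptive tables of the main
#'   cell), `exposure_summary`, `cells`, `failures` and `manifest`.
#' @export
run_study <- function(tables, manifest = run_manifest(), quiet = FALSE) {
  linkage <- linkage_report(tables$purchases, tables$stores)
  main_sample <- apply_inclusion(linkage, 0.80, quiet = TRUE)

  # Weights are held fixed across the grid at the main-analysis sample's
  # volume weights, so sensitivity cells differ only by the parameter probed.
  weights <- volume_weights(
    semi_join(tables$purchases, main_sample, by = "household_id"),
    scheme = "sample_volume"
  )

  fits <- list()
  interactions <- list()
  failures <- list()
  main_tables <- NULL
  exposure_summary <- NULL

  modal <- compute_modal_prices(tables$prices)
  sw <- store_week_magnitude(tables$prices, weights, modal_prices = modal)
  store_sets <- household_store_sets(tables$purchases, tables$stores)

  for (agg in manifest$aggregations) {
    # Weekly exposure depends on the aggregation mode but not the threshold;
    # derive it once per mode and re-annualise per threshold.
    weekly <- tryCatch(
      household_week_exposure(sw, store_sets, exposure_config(aggregation = agg)),
      error = function(e) e
    )
    if (inherits(weekly, "error")) {
      failures[[length(failures) + 1]] <- tibble(
        threshold = NA_real_, aggregation = agg, coverage = NA_real_,
        stage = "exposure", message = conditionMessage(weekly)
      )
      next
    }
    for (thr in manifest$thresholds) {
      cfg <- exposure_config(promo_threshold = thr, aggregation = agg)
      expo <- tryCatch(
        list(annual = annualize(weekly, cfg), weekly = weekly),
        error = function(e) e
      )
      if (inherits(expo, "error")) {
        failures[[length(failures) + 1]] <- tibble(
          threshold = thr, aggregation = agg, coverage = NA_real_,
          stage = "exposure", message = conditionMessage(expo)
        )
        next
      }
      for (cov_thr in manifest$coverages) {
        included <- apply_inclusion(linkage, cov_thr, quiet = TRUE)
        main <- is_main_cell(thr, agg, cov_thr)
        cell <- tryCatch({
          cohort <- build_cohort(tables, expo$annual, included)
          cell_fits <- purrr::map_dfr(manifest$exposures, function(ex) {
            f <- fit_main(cohort, exposure = ex)
            mutate(tidy(f)[1, ], n = f$n, exposure = ex, .before = 1)
          })
          if (main) {
            main_tables <- descriptive_tables(cohort, tables$purchases, tables$products)
            exposure_summary <- summarize_exposure(
              semi_join(expo$annual, included, by = "household_id")
            )
            interactions <- purrr::map(manifest$exposures, function(ex) {
              purrr::map(manifest$modifiers, function(m) {
                fit_interaction(cohort, exposure = ex, modifier = m)
              }) %>% setNames(manifest$modifiers)
            }) %>% setNames(manifest$exposures)
          }
          mutate(cell_fits, threshold = thr, aggregation = agg,
                 coverage = cov_thr, main_cell = main)
        }, error = function(e) e)
        if (inherits(cell, "error")) {
          failures[[length(failures) + 1]] <- tibble(
            threshold = thr, aggregation = agg, coverage = cov_thr,
            stage = "cohort/fit", message = conditionMessage(cell)
          )
        } else {
          fits[[length(fits) + 1]] <- cell
          if (!quiet) {
            inform(sprintf(
              "cell threshold=%.2f aggregation=%s coverage=%.2f: fitted (n=%d)%s",
              thr, agg, cov_thr, cell$n[1], if (main) " [main]" else ""
            ))
          }
        }
      }
    }
  }

  empty_fits <- tibble(
    exposure = character(), n = integer(), term = character(),
    estimate = double(), conf.low = double(), conf.high = double(),
    p.value = double(), percent_change = double(), threshold = double(),
    aggregation = character(), coverage = double(), main_cell = logical()
  )
  structure(
    list(
      fits = if (length(fits) > 0) bind_rows(fits) else empty_fits,
      interactions = interactions,
      tables = main_tables,
      exposure_summary = exposure_summary,
      failures = bind_rows(failures),
      manifest = manifest,
      n_linkage = nrow(linkage),
      retention_percent = attr(main_sample, "retention_percent")
    ),
    class = "promo_bundle"
  )
}

#' Compare the largest-discount and average-discount exposure definitions
#'
#' Side-by-side exponentiated estimates for the two store-aggregation modes
#' at every (threshold, coverage, exposure) combination present in the
#' bundle, with a flag for whether the average-mode estimate is attenuated
#' (no larger) relative to the largest-mode estimate — the direction implied
#' by the dominance of the largest-discount definition. The flag is
#' reported, not asserted: it describes the estimates, which carry sampling
#' noise.
#'
#' @param bundle A `promo_bundle` from [run_study()] whose manifest includes
#'   both aggregation modes.
#' @return A tibble with one row per cell and the `attenuated` flag.
#' @export
sensitivity_report <- function(bundle) {
  fits <- bundle$fits
  modes <- unique(fits$aggregation)
  if (nrow(fits) > 0 && !all(c("largest", "average") %in% modes)) {
    warn("bundle lacks one aggregation mode; returning a partial report")
  }
  wide <- fits %>%
    select("exposure", "threshold", "aggregation", "coverage",
           "estimate", "conf.low", "conf.high") %>%
    tidyr::pivot_wider(
      names_from = "aggregation",
      values_from = c("estimate", "conf.low", "conf.high")
    )
  if (all(c("estimate_largest", "estimate_average") %in% names(wide))) {
    wide <- mutate(wide, attenuated = .data$estimate_average <= .data$estimate_largest)
  }
  wide
}

#' Write a results bundle to disk
#'
#' Writes the grid fits, the sensitivity comparison, the descriptive tables
#' and a plain-text run log as CSV/text files. Output is a pure function of
#' the bundle, so identical runs produce byte-identical files.
#'
#' @param bundle A `promo_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$fits, file.path(dir, "fit_results.csv"), progress = FALSE)
  readr::write_csv(sensitivity_report(bundle),
                   file.path(dir, "sensitivity.csv"), progress = FALSE)
  if (!is.null(bundle$tables)) {
    readr::write_csv(bundle$tables$characteristics,
                     file.path(dir, "table1_characteristics.csv"), progress = FALSE)
    readr::write_csv(bundle$tables$purchase_summary,
                     file.path(dir, "table2_purchase_summary.csv"), progress = FALSE)
    readr::write_csv(bundle$tables$exposure_by_covariate,
                     file.path(dir, "table3_exposure_by_covariate.csv"), progress = FALSE)
  }
  if (nrow(bundle$failures) > 0) {
    readr::write_csv(bundle$failures, file.path(dir, "failures.csv"), progress = FALSE)
  }
  log_lines <- c(
    sprintf("promoscan %s", as.character(utils::packageVersion("promoscan"))),
    sprintf("households in linkage report: %d", bundle$n_linkage),
    sprintf("main-cell retention: %d%%", bundle$retention_percent),
    sprintf("grid cells fitted: %d", nrow(dplyr::distinct(
      bundle$fits, .data$threshold, .data$aggregation, .data$coverage))),
    sprintf("cell failures: %d", nrow(bundle$failures))
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.promo_bundle <- function(x, ...) {
  cat(sprintf(
    "Study bundle: %d grid cells fitted (%d failures), main cell %s\n",
    nrow(dplyr::distinct(x$fits, .data$threshold, .data$aggregation, .data$coverage)),
    nrow(x$failures),
    if (any(x$fits$main_cell)) "present" else "MISSING"
  ))
  main <- filter(x$fits, .data$main_cell)
  for (i in seq_len(nrow(main))) {
    cat(sprintf("  main %-9s exp estimate %.3f (%.3f-%.3f), n = %d\n",
                main$exposure[i], main$estimate[i], main$conf.low[i],
                main$conf.high[i], main$n[i]))
  }
  invisible(x)
}
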