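#' Forest plot of a fitted promotion model
#'
#' Exponentiated estimates with confidence intervals: the overall
#' scaled-exposure estimate and, for interaction fits, each modifier
#' stratum, against the null line at 1.
#'
#' @param object A `promo_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot promo_fit
#' @export
autoplot.promo_fit <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      x = sprintf("Multiplicative change in annual per-capita purchase (x%d %s)",
                  object$scale, object$exposure),
      y = NULL,
      title = sprintf("Promotion %s and SSB purchasing (n = %d)",
                      object$exposure, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Sensitivity-grid plot of a study bundle
#'
#' Exponentiated exposure estimates across the promotion-threshold and
#' coverage grids, by aggregation mode, with the main-analysis cell
#' highlighted.
#'
#' @param object A `promo_bundle` from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot promo_bundle
#' @export
autoplot.promo_bundle <- function(object, ...) {
  d <- object$fits
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$threshold), y = .data$estimate,
    colour = .data$aggregation, group = .data$aggregation
  )) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::geom_point(
      data = dplyr::filter(d, .data$main_cell),
      shape = 1, size = 4, colour = "black", show.legend = FALSE
    ) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$exposure),
      cols = ggplot2::vars(.data$coverage),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(
      x = "Promotion threshold",
      y = "Exponentiated exposure estimate (95% CI)",
      colour = "Store aggregation"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of annual exposure across households
#'
#' @param annual_exposure Tibble with `frequency` and `magnitude`.
#' @return A ggplot object.
#' @export
plot_exposure_distribution <- function(annual_exposure) {
  d <- tidyr::pivot_longer(annual_exposure, c("frequency", "magnitude"),
                           names_to = "exposure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$exposure), scales = "free") +
    ggplot2::labs(x = "Annual exposure", y = "Households") +
    ggplot2::theme_minimal()
}
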