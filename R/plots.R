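#' Forest plot of estimated treatment effects
#'
#' Horizontal effect-size chart with confidence-interval whiskers,
#' faceted by variable group; unreliable estimates (too few treated rows)
#' are hollow.
#'
#' @param object A `dml_effects` table (possibly several groups row-bound).
#' @param significant_only Show only effects with `p < alpha`.
#' @param alpha Significance cutoff used for colouring/filtering.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dml_effects <- function(object, significant_only = FALSE,
                                 alpha = 0.05, ...) {
  dat <- tidy(object)
  dat <- dplyr::filter(dat, !is.na(.data$estimate))
  dat$significant <- dat$p.value < alpha
  if (significant_only) dat <- dplyr::filter(dat, .data$significant)
  dat <- dplyr::mutate(dat,
                       treatment = stats::reorder(.data$treatment, .data$estimate))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$treatment)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.25, colour = "grey35") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant,
                                     shape = .data$reliable), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#B2182B",
                                            `FALSE` = "grey55"),
                                 name = sprintf("p < %g", alpha)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "estimated effect on urgency (latent scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.dml_effects
#' @export
autoplot.effect_report <- function(object, ...) {
  sig <- object$significant
  class(sig) <- c("dml_effects", class(sig))
  autoplot.dml_effects(sig, alpha = object$alpha, ...)
}

#' Bar chart of benchmark metrics
#'
#' @param metrics Tibble from [run_learner_comparison()] or
#'   [run_dml_benchmark()].
#' @param metric Which metric column to plot (default `"f1"`).
#' @return A ggplot object.
#' @export
plot_benchmark <- function(metrics, metric = "f1") {
  stopifnot(metric %in% names(metrics))
  sd_col <- paste0(metric, "_sd")
  dat <- dplyr::mutate(metrics,
                       learner = stats::reorder(.data$learner, .data[[metric]]))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data[[metric]], y = .data$learner)) +
    ggplot2::geom_col(fill = "#2166AC", width = 0.7) +
    ggplot2::labs(x = sprintf("%s (%%)", metric), y = NULL) +
    ggplot2::theme_minimal()
  if (sd_col %in% names(metrics)) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data[[metric]] - .data[[sd_col]],
                   xmax = .data[[metric]] + .data[[sd_col]]),
      height = 0.2, colour = "grey30")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
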