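# ggplot2 figures for the main result types.

#' Plot an effect profile
#'
#' Per-substitution effect sizes along the enhancer, coloured by the
#' alternate base, restricted (by default) to estimates flagged at the
#' display threshold — mirroring the usual presentation of saturation
#' mutagenesis MPRA profiles.
#'
#' @param object An `mpra_profile`.
#' @param model `"trivariate"` (default) or `"univariate"`.
#' @param significant_only Show flagged estimates only (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpra_profile
#' @export
autoplot.mpra_profile <- function(object, model = c("trivariate", "univariate"),
                                  significant_only = TRUE, ...) {
  model <- match.arg(model)
  d <- object[[model]]
  if (significant_only) d <- d[d$display, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$effect_size))
  p <- if (model == "trivariate") {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$alt), position = "identity",
                          alpha = 0.8)
  } else {
    p + ggplot2::geom_col(fill = "grey40")
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "position (bp)", y = "effect size (log2 fold change)",
                  fill = "alt base") +
    ggplot2::theme_minimal()
}

#' Plot a lag permutation test
#'
#' Permutation p-value as a function of the lag distance, with the 0.01
#' reference line.
#'
#' @param object An `mpra_lagtest` from [lag_permutation_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpra_lagtest
#' @export
autoplot.mpra_lagtest <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$p_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.01, linetype = "dashed", colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag distance (positions)", y = "permutation p-value") +
    ggplot2::theme_minimal()
}

#' Plot a cross-condition comparison
#'
#' Standardized per-position difference with its loess smooth; differential
#' clusters are shaded.
#'
#' @param object An `mpra_comparison` from [compare_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpra_comparison
#' @export
autoplot.mpra_comparison <- function(object, ...) {
  d <- object$profile
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$difference),
                        size = 0.5, alpha = 0.4, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "red",
                       na.rm = TRUE)
  if (nrow(object$clusters) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = object$clusters,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "red", alpha = 0.15,
      inherit.aes = FALSE)
  }
  p +
    ggplot2::labs(x = "position (bp)",
                  y = "standardized effect-size difference") +
    ggplot2::theme_minimal()
}

#' Plot a windowed F-statistic profile
#'
#' @param window_f Tibble from [windowed_f_profile()].
#' @return A ggplot object.
#' @export
plot_window_f <- function(window_f) {
  ggplot2::ggplot(window_f,
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$f_statistic)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.6, na.rm = TRUE) +
    ggplot2::labs(x = "window centre (bp)", y = "model F statistic") +
    ggplot2::theme_minimal()
}
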