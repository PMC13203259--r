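#' Plot a relative-week trajectory
#'
#' Raw weekly means (points) and the centered moving average (line) of a
#' standardized construct score against relative week.
#'
#' @param object A `wepa_trajectory` from [relative_week_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.wepa_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$relative_week)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_score),
                        alpha = 0.5, size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed_score),
                       linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::labs(x = "Relative week (since registration)",
                  y = "Mean standardized score",
                  title = "Relative-week trajectory") +
    ggplot2::theme_minimal()
}

#' Plot a SIMEX coefficient path
#'
#' Mean coefficient per noise multiplier with the fitted quadratic
#' extrapolation to `lambda = -1`; the corrected estimate is the open point
#' at the left.
#'
#' @param object A `simex_result` from [simex_fe()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.simex_result <- function(object, ...) {
  grid <- tibble::tibble(lambda = seq(-1, max(object$path$lambda),
                                      length.out = 100))
  qc <- object$quad_coefs
  grid$fit <- qc[[1L]] + qc[[2L]] * grid$lambda + qc[[3L]] * grid$lambda^2
  ggplot2::ggplot(object$path,
                  ggplot2::aes(x = .data$lambda, y = .data$mean_beta)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fit),
                       linetype = "dashed", colour = "#2c7fb8") +
    ggplot2::geom_point(size = 2) +
    ggplot2::annotate("point", x = -1, y = object$corrected_beta,
                      shape = 1, size = 3, colour = "#d7301f") +
    ggplot2::labs(x = expression(lambda),
                  y = "Mean coefficient",
                  title = paste0("SIMEX extrapolation: ", object$focal)) +
    ggplot2::theme_minimal()
}

#' Plot a cross-temporal stability report
#'
#' Axis-stability cosine and anchor rank-order consistency per period,
#' faceted by indicator, one line per construct.
#'
#' @param object Tibble from [stability_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_stability <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("axis_cosine", "anchor_rank_rho"),
    names_to = "indicator", values_to = "value"
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$period, y = .data$value,
                               colour = .data$construct,
                               group = .data$construct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~indicator) +
    ggplot2::labs(x = "Period", y = "Value",
                  title = "Cross-temporal stability") +
    ggplot2::theme_minimal()
}
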