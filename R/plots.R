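utils::globalVariables(c("bias_percent", "median_n", "config_id",
                         "bias", "min_n", "max_n"))

#' Plot bias detection curves
#'
#' Overlays the bias detection curves of several candidate procedures on one
#' panel: bias size (%) on the x axis, median number of results to detection
#' on the y axis. Undetected bias sizes (undefined medians) are omitted from
#' their curve.
#'
#' @param curves A single [build_bias_detection_curve()] object or a list of
#'   them.
#' @param log_y Use a log10 y scale (detection counts span orders of
#'   magnitude). Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_bias_detection_curves <- function(curves, log_y = TRUE) {
  if (inherits(curves, "bias_detection_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cu) {
    data.frame(config_id = attr(cu, "config_id"),
               bias_percent = cu$bias_percent, median_n = cu$median_n)
  }))
  df <- df[!is.na(df$median_n), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = bias_percent, y = median_n,
                                        colour = config_id)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "bias (%)", y = "median number of results to detection",
                  colour = "MA procedure") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a validation chart
#'
#' Bar chart of the median number of results needed to detect each bias size,
#' with error bars spanning the minimum and maximum over injections.
#' Undetected bias sizes appear as empty slots.
#'
#' @param chart A [build_validation_chart()] object.
#' @return A ggplot object.
#' @export
plot_validation_chart <- function(chart) {
  df <- as.data.frame(chart)
  df$bias <- factor(df$bias_percent, levels = sort(unique(df$bias_percent)))
  ggplot2::ggplot(df, ggplot2::aes(x = bias, y = median_n)) +
    ggplot2::geom_col(fill = "grey40", na.rm = TRUE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = min_n, ymax = max_n),
                           width = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "bias (%)", y = "number of results to detection",
                  title = attr(chart, "config_id")) +
    ggplot2::theme_minimal()
}
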