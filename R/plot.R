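#' Plot a control-chart result
#'
#' Quick ggplot of a `chart_result`: the charted statistic per run with
#' PASS/WARN/FAIL coloring, plus the baseline mean and 2/3-sigma limits for
#' Levey-Jennings charts or the decision interval for CUSUM.
#'
#' @param chart A `chart_result`.
#' @param baseline Optional `qc_baseline` used to draw center/limit lines on
#'   a Levey-Jennings chart.
#' @return A ggplot object.
#' @export
plot_chart <- function(chart, baseline = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    qcs_argument_error("plot_chart requires the ggplot2 package")
  kind <- attr(chart, "chart")
  df <- as.data.frame(chart)
  df$idx <- seq_len(nrow(df))
  df$y <- switch(kind,
                 LEVEY_JENNINGS = df$value,
                 CUSUM = pmax(df$cusum_pos, df$cusum_neg),
                 MOVING_RANGE = df$moving_range,
                 df$statistic)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$y)) +
    ggplot2::geom_line(color = "grey60", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(color = .data$flag), na.rm = TRUE) +
    ggplot2::scale_color_manual(values = c(PASS = "#2c7fb8", WARN = "#fe9929",
                                           FAIL = "#d7301f")) +
    ggplot2::labs(x = "run", y = kind,
                  title = paste0(attr(chart, "analyte_id"), " - ",
                                 attr(chart, "metric")),
                  color = NULL) +
    ggplot2::theme_minimal()
  if (kind == "LEVEY_JENNINGS" && !is.null(baseline) && baseline$sd > 0) {
    for (k in c(-3, -2, 0, 2, 3))
      p <- p + ggplot2::geom_hline(yintercept = baseline$mean + k * baseline$sd,
                                   linetype = if (k == 0) "solid" else "dashed",
                                   color = "grey40", linewidth = 0.3)
  }
  if (kind == "CUSUM")
    p <- p + ggplot2::geom_hline(yintercept = 5, linetype = "dashed",
                                 color = "grey40", linewidth = 0.3)
  p
}
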