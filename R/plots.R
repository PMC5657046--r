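#' Plot deletion calls along the mitochondrial genome
#'
#' Draws each called deletion as a horizontal segment spanning its deleted
#' region, at a height equal to its split-read support (log scale), colored
#' by filter status.
#'
#' @param object A `mito_calls` tibble from [call_deletions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mito_calls <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$deleted_start,
                                   xend = .data$deleted_end,
                                   y = .data$support_n,
                                   yend = .data$support_n,
                                   colour = .data$pass_filters)) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mtDNA position (bp)",
                  y = "supporting split reads (n)",
                  colour = "passes filters") +
    ggplot2::theme_minimal()
}

#' Plot a detection-power curve
#'
#' @param object A tibble from [detection_power_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mito_power_curve <- function(object, ...) {
  design <- attr(object, "design")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$heteroplasmy_pct,
                                       y = .data$detection_probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "heteroplasmy (%)", y = "detection probability",
      title = sprintf("Detection power: M = %.3g reads, E = %.0f%%, l = %d nt, threshold %d",
                      design$total_reads, 100 * design$enrichment,
                      design$read_length, design$n_min)
    ) +
    ggplot2::theme_minimal()
}
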