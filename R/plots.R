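#' Scatter plot of screen signatures
#'
#' Z in the control background against Z in the sensitized background,
#' colored by signature class, with the ZDiff hit boundaries drawn as
#' diagonal guides.
#'
#' @param hits Classified hits from [classify_signatures()] (columns
#'   `z_sensitized`, `z_control`, `class`).
#' @param thresholds A [screen_thresholds()]; used for the guide lines.
#' @return A ggplot object.
#' @export
plot_signatures <- function(hits, thresholds = screen_thresholds()) {
  check_columns(hits, c("z_sensitized", "z_control", "class"))
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$z_control,
                                     y = .data$z_sensitized,
                                     colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = thresholds$primary_up, slope = 1,
                         linetype = "dashed") +
    ggplot2::geom_abline(intercept = thresholds$primary_down, slope = 1,
                         linetype = "dashed") +
    ggplot2::labs(x = "Z (control background)",
                  y = "Z (sensitized background)",
                  colour = "class", title = "Modifier signatures") +
    ggplot2::theme_minimal()
}

#' Fold-change distribution for one condition comparison
#'
#' Histogram of log2 ratios with the calling thresholds marked.
#'
#' @param calls Output of [fold_change_call()].
#' @param threshold The linear fold threshold used for the calls.
#' @return A ggplot object.
#' @export
plot_fold_changes <- function(calls, threshold = 1.5) {
  check_columns(calls, c("ratio", "direction"))
  df <- dplyr::filter(calls, !is.na(.data$ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$ratio),
                                   fill = .data$direction)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::geom_vline(xintercept = c(-log2(threshold), log2(threshold)),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "phosphosites",
                  fill = "call", title = "Phosphosite fold changes") +
    ggplot2::theme_minimal()
}
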