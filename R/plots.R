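#' Scatter plot of a differential-expression table
#'
#' Control vs treatment normalized abundance on log10 axes, coloured by
#' significance at `alpha` combined with the 2.7-fold (|R_ln| >= 1) mark --
#' the standard view of a digital expression comparison.
#'
#' @param object A `dge_table`.
#' @param alpha Significance threshold for colouring, default 0.05.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dge_table
#' @export
autoplot.dge_table <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(unclass_keep(object))
  df$status <- ifelse(
    df$p_value < alpha & abs(df$r_ln) >= 1,
    ifelse(df$r_ln > 0, "up", "down"), "ns"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cp100k_control + 0.5, y = .data$cp100k_treatment + 0.5,
    colour = .data$status
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(up = "#D55E00", down = "#0072B2", ns = "grey60")) +
    ggplot2::labs(
      x = paste0(attr(object, "control"), " (copies/100k + 0.5)"),
      y = paste0(attr(object, "treatment"), " (copies/100k + 0.5)"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of abundance classes per library
#'
#' @param report Output of [abundance_classes()].
#' @return A ggplot object.
#' @export
plot_abundance_classes <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$class, y = .data$pct, fill = .data$library)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "copies per 100,000", y = "% of expressed tags", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of SAAT similar-hit classes
#'
#' @param families A `saat_families` object.
#' @return A ggplot object.
#' @export
plot_hit_histogram <- function(families) {
  h <- hit_histogram(families)
  h$similar_hits <- factor(h$similar_hits, levels = h$similar_hits)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$similar_hits, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "similar UniTags within the library", y = "% of UniTags") +
    ggplot2::theme_minimal()
}

#' Top categories of a GSR analysis
#'
#' @param object A `gsr_result`.
#' @param top_n Number of categories shown (by p-value), default 20.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gsr_result
#' @export
autoplot.gsr_result <- function(object, top_n = 20, ...) {
  df <- head(arrange(as_tibble(unclass_keep(object)), .data$p_value), top_n)
  df$category <- factor(df$category, levels = rev(df$category))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_value), y = .data$category, fill = .data$is_custom
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL, fill = "custom") +
    ggplot2::theme_minimal()
}

#' Bar chart of a UniTag-per-EST multiplicity report
#'
#' @param report Output of [multiplicity_report()].
#' @return A ggplot object.
#' @export
plot_multiplicity <- function(report) {
  report$class <- factor(report$class, levels = report$class)
  ggplot2::ggplot(report, ggplot2::aes(x = .data$class, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "UniTags per EST", y = "% of matched ESTs") +
    ggplot2::theme_minimal()
}
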