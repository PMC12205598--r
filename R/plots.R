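# ggplot2 views of the main result types.

#' Histogram of redistribution scores with the classification threshold
#'
#' @param scores Tibble from [redistribution_scores()] /
#'   [flag_redistributed()].
#' @param threshold Numeric threshold or `roc_threshold`; defaults to the
#'   `threshold` column when present.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_score_histogram <- function(scores, threshold = NULL, bins = 30) {
  if (is.null(threshold) && "threshold" %in% names(scores))
    threshold <- scores$threshold[1]
  if (inherits(threshold, "roc_threshold")) threshold <- threshold$threshold
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey55", color = "white") +
    ggplot2::labs(x = "redistribution score", y = "proteins") +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  p
}

#' Volcano plot of abundance changes
#'
#' @param ab Tibble from [abundance_table()].
#' @param lfc_min,q_max Class thresholds drawn as guides.
#' @return A ggplot object.
#' @export
plot_volcano <- function(ab, lfc_min = 0.2, q_max = 0.05) {
  ggplot2::ggplot(ab, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_q,
                                   color = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(q_max), linetype = "dotted") +
    ggplot2::scale_color_manual(values = c(increase = "#d95f02",
                                           decrease = "#1b9e77", ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (deletion vs wild type)",
                  y = "-log10 q") +
    ggplot2::theme_minimal()
}

#' Plot a PCA view of a pair's redistribution
#'
#' Cells colored by protein, shaped by background, with
#' wild-type-to-deletion centroid arrows.
#'
#' @param object A `redistribution_pca` object from [pca_view()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.redistribution_pca <- function(object, ...) {
  ve <- object$var_explained
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                    color = .data$protein,
                                    shape = .data$background)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
  if (all(c("PC1_wt", "PC1_deletion") %in% names(object$arrows))) {
    p <- p + ggplot2::geom_segment(
      data = object$arrows,
      ggplot2::aes(x = .data$PC1_wt, y = .data$PC2_wt,
                   xend = .data$PC1_deletion, yend = .data$PC2_deletion,
                   color = .data$protein),
      inherit.aes = FALSE,
      arrow = ggplot2::arrow(length = ggplot2::unit(0.2, "cm")),
      linewidth = 0.8)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
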