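#' Abundance score of a condition
#'
#' Mean raw pixel intensity across all the pixels of all the cell frames in
#' the condition (pixel-weighted when frame sizes differ). Raw
#' (background-subtracted, unnormalized) intensities must be used.
#'
#' @param frames List of raw-intensity frame matrices.
#' @return Scalar abundance score (arbitrary units).
#' @export
abundance_score <- function(frames) {
  if (length(frames) == 0) stop("no frames", call. = FALSE)
  tot <- sum(vapply(frames, sum, 0))
  n <- sum(vapply(frames, length, 0L))
  tot / n
}

#' Log2 fold change between background abundance scores
#'
#' `log2(score_del + 1) - log2(score_wt + 1)`: positive values mean the
#' protein's abundance increased upon deletion of its paralog.
#'
#' @param score_wt,score_del Nonnegative abundance scores.
#' @return Scalar log2 fold change.
#' @export
log2fc <- function(score_wt, score_del) {
  if (any(c(score_wt, score_del) < 0)) stop("abundance scores must be nonnegative")
  log2(score_del + 1) - log2(score_wt + 1)
}

#' Mann-Whitney test of per-cell intensities between backgrounds
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test on per-cell mean raw
#' intensities, cells pooled across replicates. With fewer than `min_n` cells
#' in either group the comparison is flagged and `NA` returned.
#'
#' @param per_cell_wt,per_cell_del Numeric vectors of per-cell mean
#'   intensities.
#' @param min_n Minimum cells per group.
#' @return Two-sided p-value, or `NA` (with a warning) when underpowered.
#' @export
abundance_test <- function(per_cell_wt, per_cell_del, min_n = 3L) {
  if (length(per_cell_wt) < min_n || length(per_cell_del) < min_n) {
    warning("fewer than ", min_n, " cells in a group: p flagged as missing")
    return(NA_real_)
  }
  if (length(unique(c(per_cell_wt, per_cell_del))) == 1L) return(1)  # no separation
  suppressWarnings(
    wilcox.test(per_cell_wt, per_cell_del, alternative = "two.sided")$p.value
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted q-values.
#' @export
fdr_bh <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Classify an abundance change
#'
#' `increase` when `log2fc >= lfc_min` and `q < q_max`; `decrease` when
#' `log2fc <= -lfc_min` and `q < q_max`; otherwise `ns`. The significance
#' gate uses the FDR-adjusted q-value.
#'
#' @param log2fc,q Numeric vectors (recycled to common length).
#' @param lfc_min Absolute log2 fold-change threshold.
#' @param q_max Significance threshold on q.
#' @return Character vector in `{"increase", "decrease", "ns"}`.
#' @export
classify_abundance <- function(log2fc, q, lfc_min = 0.2, q_max = 0.05) {
  sig <- !is.na(q) & q < q_max
  dplyr::case_when(
    sig & log2fc >= lfc_min ~ "increase",
    sig & log2fc <= -lfc_min ~ "decrease",
    TRUE ~ "ns"
  )
}

#' Per-protein abundance change table
#'
#' Computes the abundance score per background, the log2 fold change, the
#' Mann-Whitney p-value on per-cell mean intensities, the BH-adjusted q over
#' all proteins, the resulting class, and volcano-plot coordinates.
#'
#' @param cells Per-cell tibble with `protein`, `background` and
#'   `intensity_mean` (per-cell mean raw frame intensity).
#' @param lfc_min,q_max Class thresholds (see [classify_abundance()]).
#' @return Tibble with one row per protein: `protein`, `score_wt`,
#'   `score_del`, `log2fc`, `p`, `q`, `class`, `neg_log10_q`.
#' @export
abundance_table <- function(cells, lfc_min = 0.2, q_max = 0.05) {
  stopifnot(all(c("protein", "background", "intensity_mean") %in% names(cells)))
  out <- cells |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      score_wt = mean(.data$intensity_mean[.data$background == "wt"]),
      score_del = mean(.data$intensity_mean[.data$background == "deletion"]),
      p = abundance_test(.data$intensity_mean[.data$background == "wt"],
                         .data$intensity_mean[.data$background == "deletion"]),
      .groups = "drop") |>
    dplyr::mutate(log2fc = log2fc(.data$score_wt, .data$score_del),
                  q = fdr_bh(.data$p),
                  class = classify_abundance(.data$log2fc, .data$q, lfc_min, q_max),
                  neg_log10_q = -log10(.data$q))
  dplyr::relocate(out, "log2fc", .after = "score_del")
}
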