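#' Per-condition embedding centroids
#'
#' Pools all cells of each protein x background condition (across replicates
#' and fields) and takes the arithmetic mean of every embedding feature,
#' giving one 128-dimensional centroid per condition.
#'
#' @param cells Tibble with `protein`, `background` and feature columns
#'   `f000`-`f127`.
#' @return Tibble with `protein`, `background`, `n_cells` and the mean
#'   feature columns.
#' @export
condition_centroids <- function(cells) {
  fc <- feature_cols()
  stopifnot(all(c("protein", "background", fc) %in% names(cells)))
  if (nrow(cells) == 0) stop("no cells to average", call. = FALSE)
  cells |>
    dplyr::group_by(.data$protein, .data$background) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     dplyr::across(dplyr::all_of(fc), mean),
                     .groups = "drop")
}

#' Redistribution score between two condition centroids
#'
#' The Euclidean distance between a protein's wild-type-background centroid
#' and its paralog-deletion-background centroid: a combined, non-directional
#' measure of localization and abundance change.
#'
#' @param c_wt,c_del One-row centroid tibbles from [condition_centroids()]
#'   for the same protein in the two backgrounds.
#' @return Nonnegative scalar.
#' @export
redistribution_score <- function(c_wt, c_del) {
  stopifnot(nrow(c_wt) == 1, nrow(c_del) == 1)
  if (!identical(c_wt$protein, c_del$protein))
    stop("centroids belong to different proteins", call. = FALSE)
  fc <- feature_cols()
  sqrt(sum((as.numeric(c_wt[1, fc]) - as.numeric(c_del[1, fc]))^2))
}

#' Redistribution scores for every protein in a cell table
#'
#' @param cells Per-cell tibble with `protein`, `background` and embedding
#'   columns (or an already-computed [condition_centroids()] table).
#' @return Tibble with `protein`, `n_cells_wt`, `n_cells_del`, `score`.
#'   Proteins lacking one of the two backgrounds are dropped.
#' @export
redistribution_scores <- function(cells) {
  cent <- if ("n_cells" %in% names(cells)) cells else condition_centroids(cells)
  fc <- feature_cols()
  wt <- dplyr::filter(cent, .data$background == "wt")
  del <- dplyr::filter(cent, .data$background == "deletion")
  joined <- dplyr::inner_join(wt, del, by = "protein", suffix = c("_wt", "_del"))
  if (nrow(joined) == 0) {
    return(tibble::tibble(protein = character(), n_cells_wt = integer(),
                          n_cells_del = integer(), score = numeric()))
  }
  D <- as.matrix(joined[, paste0(fc, "_wt")]) - as.matrix(joined[, paste0(fc, "_del")])
  tibble::tibble(protein = joined$protein,
                 n_cells_wt = joined$n_cells_wt,
                 n_cells_del = joined$n_cells_del,
                 score = sqrt(rowSums(D^2)))
}

#' Select a classification threshold by ROC analysis
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' pooled scores; a protein is flagged when its score exceeds the threshold.
#' Among candidates achieving the minimal false positive rate on the false
#' set, ties are broken by maximal true positive rate, then by the smallest
#' threshold. This prioritizes specificity: with well-separated sets the
#' returned cut has FPR 0 while keeping sensitivity maximal.
#'
#' @param scores_true Scores of confirmed redistributed proteins.
#' @param scores_false Scores of negative-control proteins.
#' @return Object of class `roc_threshold` with elements `threshold`, `fpr`,
#'   `tpr`, `fnr`, and the full candidate table. [tidy()] returns the
#'   candidate table; [glance()] the chosen operating point.
#' @export
select_threshold <- function(scores_true, scores_false) {
  if (length(scores_true) == 0 || length(scores_false) == 0)
    stop("both score sets must be nonempty", call. = FALSE)
  pooled <- sort(unique(c(scores_true, scores_false)))
  cand <- if (length(pooled) > 1) (head(pooled, -1) + tail(pooled, -1)) / 2
          else pooled - 0.5
  grid <- tibble::tibble(
    threshold = cand,
    fpr = vapply(cand, function(t) mean(scores_false > t), 0),
    tpr = vapply(cand, function(t) mean(scores_true > t), 0)
  )
  best <- grid |>
    dplyr::filter(.data$fpr == min(.data$fpr)) |>
    dplyr::filter(.data$tpr == max(.data$tpr)) |>
    dplyr::slice_min(.data$threshold, n = 1)
  structure(list(threshold = best$threshold, fpr = best$fpr, tpr = best$tpr,
                 fnr = 1 - best$tpr, n_true = length(scores_true),
                 n_false = length(scores_false), candidates = grid,
                 tie_break = "max TPR, then smallest threshold"),
            class = "roc_threshold")
}

#' @export
print.roc_threshold <- function(x, ...) {
  cat(sprintf("<roc_threshold> threshold = %.4g (FPR %.3f, TPR %.3f, FNR %.3f; %d true / %d false)\n",
              x$threshold, x$fpr, x$tpr, x$fnr, x$n_true, x$n_false))
  invisible(x)
}

#' @export
tidy.roc_threshold <- function(x, ...) x$candidates

#' @export
glance.roc_threshold <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, fpr = x$fpr, tpr = x$tpr,
                 fnr = x$fnr, n_true = x$n_true, n_false = x$n_false)
}

#' Reference redistribution threshold from the original screen
#'
#' Score cut (4.73) used to annotate report figures; it is a fixed reference
#' constant, never recomputed from synthetic data.
#' @return Scalar.
#' @export
ref_redistribution_threshold <- function() 4.73

#' Flag redistributed proteins at a threshold
#'
#' @param scores Tibble from [redistribution_scores()].
#' @param threshold Numeric threshold or a `roc_threshold` object.
#' @return `scores` with `threshold` and `flag_redistributed` columns
#'   (`score > threshold`).
#' @export
flag_redistributed <- function(scores, threshold) {
  if (inherits(threshold, "roc_threshold")) threshold <- threshold$threshold
  dplyr::mutate(scores, threshold = threshold,
                flag_redistributed = .data$score > threshold)
}

#' PCA view of one pair's four conditions
#'
#' Z-score normalizes each embedding feature over the pooled cells (dropping
#' zero-variance features), projects onto the first two principal components,
#' and records the wild-type-to-deletion centroid arrow per protein. The PCA
#' serves visualization only; redistribution scores are computed in the
#' original feature space.
#'
#' @param cells Per-cell tibble of the pair's conditions with embedding
#'   columns.
#' @return Object of class `redistribution_pca`: list with `scores` (cell
#'   metadata + `PC1`, `PC2`), `var_explained` (percent, length 2) and
#'   `arrows` (per protein: centroid start/end in PC space).
#' @export
pca_view <- function(cells) {
  fc <- feature_cols()
  stopifnot(all(fc %in% names(cells)))
  if (nrow(cells) < 3) stop("need at least 3 cells for a PCA view", call. = FALSE)
  X <- as.matrix(cells[, fc])
  v <- apply(X, 2, sd)
  keep <- v > 0
  if (!any(keep)) stop("degenerate input: all cells identical", call. = FALSE)
  Z <- scale(X[, keep, drop = FALSE])
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  if (ncol(pc$x) < 2) {  # rank-1 input: pad a zero second component
    pc$x <- cbind(pc$x, 0)
    pc$rotation <- cbind(pc$rotation, 0)
    pc$sdev <- c(pc$sdev, 0)
  }
  # deterministic sign: largest-magnitude loading positive
  for (k in 1:2) {
    l <- pc$rotation[, k]
    if (l[which.max(abs(l))] < 0) {
      pc$rotation[, k] <- -l
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- dplyr::bind_cols(
    dplyr::select(cells, dplyr::any_of(c("cell_id", "protein", "background",
                                         "replicate", "field"))),
    tibble::tibble(PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  )
  arrows <- scores |>
    dplyr::group_by(.data$protein, .data$background) |>
    dplyr::summarise(PC1 = mean(.data$PC1), PC2 = mean(.data$PC2), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "background", values_from = c("PC1", "PC2"))
  structure(list(scores = scores, var_explained = ve[1:2], arrows = arrows),
            class = "redistribution_pca")
}
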