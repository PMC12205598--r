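# Network feature association: PPI/GI binning of paralogs, colocalization,
# enrichment and group comparisons.

as_ppi_graph <- function(graph) {
  if (inherits(graph, "igraph")) return(graph)
  stopifnot(is.data.frame(graph), all(c("gene_a", "gene_b") %in% names(graph)))
  igraph::graph_from_data_frame(graph[, c("gene_a", "gene_b")], directed = FALSE)
}

neighbor_set <- function(g, gene) {
  if (!gene %in% igraph::V(g)$name) return(character())
  setdiff(names(igraph::neighbors(g, gene)), gene)
}

#' Subset genetic-interaction edges at a stringency level
#'
#' Levels: lenient (`p < 0.05`), intermediate (`p < 0.05` and `|epsilon| >
#' 0.08`), stringent (`p < 0.05` and `epsilon > 0.16` or `epsilon < -0.12`),
#' synthetic_lethal (`p < 0.05` and `epsilon < -0.35`).
#'
#' @param edges Tibble with `gene_a`, `gene_b`, `epsilon`, `p`.
#' @param level One of `"lenient"`, `"intermediate"`, `"stringent"`,
#'   `"synthetic_lethal"`.
#' @return Filtered tibble.
#' @export
gi_subset <- function(edges, level = c("lenient", "intermediate", "stringent",
                                       "synthetic_lethal")) {
  level <- match.arg(level)
  stopifnot(all(c("epsilon", "p") %in% names(edges)))
  keep <- switch(level,
    lenient = edges$p < 0.05,
    intermediate = edges$p < 0.05 & abs(edges$epsilon) > 0.08,
    stringent = edges$p < 0.05 & (edges$epsilon > 0.16 | edges$epsilon < -0.12),
    synthetic_lethal = edges$p < 0.05 & edges$epsilon < -0.35
  )
  edges[keep, , drop = FALSE]
}

#' Shared interactors of paralog pairs, with a median split
#'
#' Counts interactors common to both members of each pair (the members
#' themselves excluded) and bins pairs below-or-equal vs above the cohort
#' median into `low` / `high`; counts exactly at the median go to `low` and
#' are reported via the `at_median` column.
#'
#' @param graph An igraph object or an edge tibble (`gene_a`, `gene_b`).
#' @param pairs Tibble with `gene_a`, `gene_b` (one row per pair). Genes
#'   absent from the graph contribute an empty neighborhood.
#' @return `pairs` with `shared_n`, `bin`, `at_median` columns.
#' @export
shared_interactors <- function(graph, pairs) {
  g <- as_ppi_graph(graph)
  shared_n <- purrr::map2_int(pairs$gene_a, pairs$gene_b, function(a, b) {
    length(setdiff(intersect(neighbor_set(g, a), neighbor_set(g, b)), c(a, b)))
  })
  med <- median(shared_n)
  dplyr::mutate(pairs, shared_n = shared_n,
                bin = ifelse(shared_n > med, "high", "low"),
                at_median = shared_n == med)
}

#' Shortest-path class of paralog pairs
#'
#' Breadth-first shortest path length between pair members in an undirected
#' network, classed as `1` (direct edge) or `1+` (longer or disconnected).
#' Disconnected or absent genes get a missing length and class `1+`.
#'
#' @inheritParams shared_interactors
#' @return `pairs` with `path_length` (NA when disconnected/absent) and
#'   `path_class` columns.
#' @export
shortest_path_class <- function(graph, pairs) {
  g <- as_ppi_graph(graph)
  len <- purrr::map2_dbl(pairs$gene_a, pairs$gene_b, function(a, b) {
    vs <- igraph::V(g)$name
    if (!a %in% vs || !b %in% vs) return(NA_real_)
    d <- igraph::distances(g, v = a, to = b)[1, 1]
    if (is.infinite(d)) NA_real_ else d
  })
  dplyr::mutate(pairs, path_length = len,
                path_class = ifelse(!is.na(len) & len == 1, "1", "1+"))
}

#' Jaccard colocalization of two compartment sets
#'
#' Index = `100 * |A intersect B| / |A union B|`; two proteins are
#' colocalized when the index reaches 50 (boundary inclusive).
#'
#' @param setA,setB Nonempty character vectors of compartment names.
#' @return List with `index` and `colocalized`.
#' @export
jaccard_colocalized <- function(setA, setB) {
  if (length(setA) == 0 || length(setB) == 0)
    stop("compartment sets must be nonempty", call. = FALSE)
  idx <- 100 * length(intersect(setA, setB)) / length(union(setA, setB))
  list(index = idx, colocalized = idx >= 50)
}

#' Private interactors of a paralog pair
#'
#' Neighbors unique to each member: `N(a) \ (N(b) U {b})` and
#' `N(b) \ (N(a) U {a})`.
#'
#' @inheritParams shared_interactors
#' @param gene_a,gene_b The pair members.
#' @return List with `private_a` and `private_b` character vectors.
#' @export
private_interactors <- function(graph, gene_a, gene_b) {
  g <- as_ppi_graph(graph)
  na <- neighbor_set(g, gene_a); nb <- neighbor_set(g, gene_b)
  list(private_a = setdiff(na, c(nb, gene_b)),
       private_b = setdiff(nb, c(na, gene_a)))
}

#' Fisher's exact association between two per-protein flags
#'
#' Builds the 2x2 table of `flag` (e.g. redistributed) against `feature`
#' (e.g. has a colocalized private interactor) and reports the sample odds
#' ratio `(a*d)/(b*c)` with the two-sided Fisher exact p-value. A zero
#' margin leaves the odds ratio undefined (`NA`); a zero off-diagonal cell
#' with nonzero margins gives `Inf`.
#'
#' @param flag,feature Logical vectors of equal length.
#' @return One-row tibble: `a`, `b`, `c`, `d`, `odds_ratio`, `p`.
#' @export
enrichment_fisher <- function(flag, feature) {
  stopifnot(length(flag) == length(feature))
  a <- sum(flag & feature); b <- sum(flag & !feature)
  cc <- sum(!flag & feature); d <- sum(!flag & !feature)
  tab <- matrix(c(a, cc, b, d), 2)
  or <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_
        else if (b * cc == 0) Inf else (a * d) / (b * cc)
  p <- if (is.na(or)) NA_real_ else fisher.test(tab, alternative = "two.sided")$p.value
  tibble::tibble(a = a, b = b, c = cc, d = d, odds_ratio = or, p = p)
}

#' Compare redistribution scores between feature bins
#'
#' Two-sided Mann-Whitney U test of a score column between the two levels of
#' each binning column. Comparisons with an empty bin are skipped (reported
#' with `NA` and a message).
#'
#' @param data Tibble holding the score and binning columns.
#' @param score Name of the numeric score column.
#' @param bins Character vector of binning column names (each with exactly
#'   two non-NA levels).
#' @return Tibble: `comparison`, `level_a`, `level_b`, `n_a`, `n_b`,
#'   `median_a`, `median_b`, `p`.
#' @export
group_compare <- function(data, score, bins) {
  purrr::map_dfr(bins, function(bn) {
    x <- data[[score]]; gview <- data[[bn]]
    ok <- !is.na(gview) & !is.na(x)
    lev <- sort(unique(gview[ok]))
    if (length(lev) != 2 || !all(table(gview[ok]) > 0)) {
      message("comparison skipped (needs two nonempty bins): ", bn)
      return(tibble::tibble(comparison = bn, level_a = NA_character_,
                            level_b = NA_character_, n_a = 0L, n_b = 0L,
                            median_a = NA_real_, median_b = NA_real_,
                            p = NA_real_))
    }
    xa <- x[ok & gview == lev[1]]; xb <- x[ok & gview == lev[2]]
    tibble::tibble(comparison = bn, level_a = as.character(lev[1]),
                   level_b = as.character(lev[2]),
                   n_a = length(xa), n_b = length(xb),
                   median_a = median(xa), median_b = median(xb),
                   p = suppressWarnings(wilcox.test(xa, xb)$p.value))
  })
}

#' Spearman correlation of morphology and embedding features
#'
#' Correlates every morphology feature with every embedding feature across
#' aligned cells (Spearman, two-sided), adjusts all p-values by BH, and
#' summarizes the fraction significant. Constant columns yield missing
#' correlations.
#'
#' @param morph Tibble of morphology features (numeric columns only are
#'   used), one row per cell.
#' @param embeddings Tibble or matrix of embedding features aligned
#'   row-by-row with `morph`.
#' @param q_max Significance threshold on the BH-adjusted p.
#' @return List with `correlations` (long tibble: `morph_feature`,
#'   `embedding_feature`, `rho`, `p`, `q`) and `fraction_significant`.
#' @export
morphology_correlation <- function(morph, embeddings, q_max = 0.05) {
  M <- as.data.frame(morph)[vapply(as.data.frame(morph), is.numeric, TRUE)]
  E <- as.data.frame(embeddings)
  stopifnot(nrow(M) == nrow(E))
  res <- tidyr::expand_grid(morph_feature = names(M), embedding_feature = names(E))
  stat <- purrr::map2(res$morph_feature, res$embedding_feature, function(mf, ef) {
    x <- M[[mf]]; y <- E[[ef]]
    if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  })
  res$rho <- vapply(stat, `[`, 0, 1)
  res$p <- vapply(stat, `[`, 0, 2)
  res$q <- fdr_bh(res$p)
  list(correlations = res,
       fraction_significant = mean(res$q < q_max, na.rm = TRUE))
}
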