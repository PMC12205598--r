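gi_tbl <- function(eps, p) tibble::tibble(gene_a = "a", gene_b = "b",
                                          epsilon = eps, p = p)

test_that("genetic-interaction subsets apply the published thresholds and nest", {
  expect_equal(nrow(gi_subset(gi_tbl(-0.15, 0.01), "stringent")), 1)
  expect_equal(nrow(gi_subset(gi_tbl(0.10, 0.2), "lenient")), 0)
  deep <- gi_tbl(-0.40, 0.01)
  for (lv in c("lenient", "intermediate", "stringent", "synthetic_lethal"))
    expect_equal(nrow(gi_subset(deep, lv)), 1)
  expect_error(gi_subset(deep, "bogus"))
  # nesting property over random edges
  set.seed(1)
  edges <- tibble::tibble(gene_a = "a", gene_b = "b",
                          epsilon = rnorm(500, 0, 0.2), p = runif(500))
  len <- gi_subset(edges, "lenient"); int <- gi_subset(edges, "intermediate")
  str <- gi_subset(edges, "stringent"); sl <- gi_subset(edges, "synthetic_lethal")
  expect_true(all(str$epsilon %in% int$epsilon))
  expect_true(all(int$epsilon %in% len$epsilon))
  expect_true(all(sl$epsilon %in% str$epsilon))
})

test_that("shared interactors and the median split follow the counting rules", {
  edges <- tibble::tibble(
    gene_a = c("a", "a", "a", "b", "b", "b", "c", "d", "e", "f", "g", "h"),
    gene_b = c("x", "y", "z", "y", "z", "w", "x", "x", "u", "u", "v", "t"))
  pairs <- tibble::tibble(pair_id = c("ab", "cd", "ef", "gh"),
                          gene_a = c("a", "c", "e", "g"),
                          gene_b = c("b", "d", "f", "h"))
  sh <- shared_interactors(edges, pairs)
  expect_equal(sh$shared_n, c(2L, 1L, 1L, 0L))
  # median is 1; only counts above it are high, ties go low and are flagged
  expect_equal(sh$bin, c("high", "low", "low", "low"))
  expect_equal(sh$at_median, c(FALSE, TRUE, TRUE, FALSE))
  # absent gene contributes an empty neighborhood
  pairs2 <- tibble::tibble(pair_id = "zz", gene_a = "nope", gene_b = "a")
  expect_equal(shared_interactors(edges, pairs2)$shared_n, 0L)
})

test_that("shortest-path classes distinguish direct edges from longer paths", {
  edges <- tibble::tibble(gene_a = c("a", "x", "c", "d"),
                          gene_b = c("x", "b", "d", "q"))
  pairs <- tibble::tibble(pair_id = c("ab", "cd", "aq"),
                          gene_a = c("a", "c", "a"), gene_b = c("b", "d", "q"))
  sp <- shortest_path_class(edges, pairs)
  expect_equal(sp$path_length, c(2, 1, NA))   # a-x-b; direct; disconnected
  expect_equal(sp$path_class, c("1+", "1", "1+"))
})

test_that("Jaccard colocalization is symmetric, bounded, and boundary-inclusive", {
  expect_equal(jaccard_colocalized(c("er", "cyto"), c("er", "cyto")),
               list(index = 100, colocalized = TRUE))
  j <- jaccard_colocalized(c("a", "b"), c("b", "c"))
  expect_equal(j$index, 100 / 3, tolerance = 1e-9)
  expect_false(j$colocalized)
  j2 <- jaccard_colocalized("a", c("a", "b"))
  expect_equal(j2$index, 50)
  expect_true(j2$colocalized)
  expect_equal(jaccard_colocalized(c("x", "y"), c("y", "x"))$index,
               jaccard_colocalized(c("y", "x"), c("x", "y"))$index)
  expect_error(jaccard_colocalized(character(), "a"), "nonempty")
})

test_that("private interactors exclude shared neighbors and the partner itself", {
  edges <- tibble::tibble(gene_a = c("a", "a", "b", "b", "a"),
                          gene_b = c("x", "y", "y", "z", "b"))
  pr <- private_interactors(edges, "a", "b")
  expect_equal(pr$private_a, "x")
  expect_equal(pr$private_b, "z")
  same <- tibble::tibble(gene_a = c("a", "b"), gene_b = c("x", "x"))
  pr2 <- private_interactors(same, "a", "b")
  expect_length(pr2$private_a, 0)
  expect_length(pr2$private_b, 0)
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  flag <- rep(c(TRUE, FALSE), each = 10)
  res <- enrichment_fisher(flag, flag)      # [[10, 0], [0, 10]]
  expect_equal(res$odds_ratio, Inf)
  oracle <- sum(stats::dhyper(c(0, 10), 10, 10, 10))  # exact enumeration
  expect_equal(res$p, oracle, tolerance = 1e-12)
  even <- enrichment_fisher(rep(c(TRUE, FALSE), 10), rep(c(TRUE, TRUE, FALSE, FALSE), 5))
  expect_equal(even$odds_ratio, 1)
  expect_equal(even$p, 1)
  # zero margin: OR undefined
  zm <- enrichment_fisher(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  expect_true(is.na(zm$odds_ratio))
  # invariance to transposing the table
  set.seed(2)
  f1 <- runif(60) < 0.5; f2 <- runif(60) < 0.4
  expect_equal(enrichment_fisher(f1, f2)$odds_ratio,
               enrichment_fisher(f2, f1)$odds_ratio)
  expect_equal(enrichment_fisher(f1, f2)$p, enrichment_fisher(f2, f1)$p)
})

test_that("independence keeps Fisher p-values uniform", {
  set.seed(6)
  ps <- replicate(400, {
    enrichment_fisher(runif(200) < 0.5, runif(200) < 0.5)$p
  })
  # discrete p-values are conservative; check no excess of small ones
  expect_lt(mean(ps < 0.05), 0.07)
})

test_that("group comparisons detect shifts and skip empty bins", {
  df <- tibble::tibble(score = c(rnorm(30), rnorm(30, 2)),
                       bin = rep(c("low", "high"), each = 30))
  res <- group_compare(df, "score", "bin")
  expect_lt(res$p, 0.01)
  one <- tibble::tibble(score = rnorm(10), bin = "low")
  expect_message(res2 <- group_compare(one, "score", "bin"), "skipped")
  expect_true(is.na(res2$p))
  # identical bins give p near 1
  same <- tibble::tibble(score = rep(c(1, 2, 3), 10),
                         bin = rep(c("a", "b"), 15))
  expect_gt(group_compare(same, "score", "bin")$p, 0.5)
})

test_that("shifted bins are detected with high power", {
  set.seed(13)
  hits <- replicate(60, {
    df <- tibble::tibble(score = c(rnorm(30), rnorm(30, 2)),
                         bin = rep(c("low", "high"), each = 30))
    group_compare(df, "score", "bin")$p < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("morphology-embedding correlations respect rank invariance", {
  set.seed(3)
  n <- 300
  area <- rlnorm(n, 5, 0.3)
  emb <- tibble::tibble(e1 = area, e2 = log(area) + 5, e3 = rnorm(n),
                        e4 = rep(1, n))
  morph <- tibble::tibble(area = area, other = rnorm(n))
  mc <- morphology_correlation(morph, emb)
  cors <- mc$correlations
  expect_equal(cors$rho[cors$morph_feature == "area" & cors$embedding_feature == "e1"], 1)
  # monotone transform preserves Spearman rho exactly
  expect_equal(cors$rho[cors$morph_feature == "area" & cors$embedding_feature == "e2"], 1)
  expect_true(is.na(cors$rho[cors$embedding_feature == "e4"][1]))
  indep <- abs(cors$rho[cors$morph_feature == "other" & cors$embedding_feature %in% c("e1", "e3")])
  expect_true(all(indep < 0.15))
})

test_that("independent feature columns stay uncorrelated", {
  set.seed(4)
  n <- 1000
  M <- tibble::as_tibble(matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("m", 1:4))))
  E <- tibble::as_tibble(matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("e", 1:10))))
  mc <- morphology_correlation(M, E)
  expect_gte(mean(abs(mc$correlations$rho) < 0.1, na.rm = TRUE), 0.95)
  expect_lt(mc$fraction_significant, 0.1)
})
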