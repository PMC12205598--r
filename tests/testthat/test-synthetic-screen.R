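test_that("empty design yields an empty screen and truth table", {
  d <- screen_design(0, 0)
  tr <- sim_truth(d)
  expect_equal(nrow(tr), 0)
  scr <- generate_screen(d, tr, seed = 1)
  expect_length(scr$images, 0)
})

test_that("render_cell validates abundance and compartment names", {
  expect_error(render_cell("cytoplasm", 0), "positive")
  expect_error(render_cell("cytoplasm", -3), "positive")
  expect_error(render_cell("mitochondria", 10), "unknown compartment")
  expect_error(render_cell(c(ER = 0.4, cytoplasm = 0.4), 10), "sum to 1")
})

test_that("nucleus template concentrates signal in the inner disk at zero noise", {
  geom <- list(a = 20, b = 20, theta = 0)
  cell <- render_cell("nucleus", 100, geom)
  n <- nrow(cell$pixels); ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  inner <- d <= 0.4 * 20 & cell$stencil
  frac <- sum(cell$pixels[inner]) / sum(cell$pixels[cell$stencil])
  expect_gt(frac, 0.7)
})

test_that("ER ring is bright relative to the cell interior at zero noise", {
  geom <- list(a = 20, b = 20, theta = 0)
  cell <- render_cell("ER", 100, geom)
  n <- nrow(cell$pixels); ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  ring <- d >= 0.55 * 20 & d <= 0.85 * 20
  interior <- d < 0.55 * 20
  expect_gt(mean(cell$pixels[ring]) / mean(cell$pixels[interior]), 2)
})

test_that("rendered mean intensity tracks the abundance parameter exactly at zero noise", {
  geom <- list(a = 14, b = 11, theta = 0.4)
  for (comp in c("cytoplasm", "nucleus", "ER", "vacuole")) {
    means <- vapply(c(50, 100, 200, 500), function(A) {
      cell <- render_cell(comp, A, geom)
      mean(cell$pixels[cell$stencil])
    }, 0)
    slope <- coef(lm(means ~ 0 + c(50, 100, 200, 500)))[[1]]
    expect_lt(abs(slope - 1), 0.05)
  }
  # stencil is a single 4-connected region
  cell <- render_cell("cytoplasm", 10, geom)
  expect_equal(max(paralogshift:::.cc_label(cell$stencil, 4L)), 1L)
})

test_that("a planted 2x abundance effect is recovered from rendered cells", {
  set.seed(42)
  geom <- list(a = 13, b = 11, theta = 0)
  mean_fg <- function(A, n) {
    mean(vapply(seq_len(n), function(i) {
      cell <- render_cell("cytoplasm", A * exp(rnorm(1, 0, 0.2)), geom,
                          noise_params = list(gain = 1, read_sd = 2))
      mean(cell$pixels[cell$stencil])
    }, 0))
  }
  ratio <- mean_fg(800, 500) / mean_fg(400, 500)
  expect_gte(ratio, 1.8)
  expect_lte(ratio, 2.2)
})

test_that("per-condition cell counts respect the configured field range", {
  d <- screen_design(1, 0)  # defaults: 3 replicates, 4 fields, 50-100 cells
  tr <- sim_truth(d, seed = 3)
  n <- 0L
  for (r in 1:3) for (f in 1:4) {
    g <- generate_condition_image(d, tr, "P01", "wt", r, f, seed = 3)
    expect_gte(g$meta$n_cells, 50)
    expect_lte(g$meta$n_cells, 100)
    expect_equal(max(g$mask), g$meta$n_cells)  # consecutive instance labels
    n <- n + g$meta$n_cells
  }
  expect_gte(n, 600); expect_lte(n, 1200)
})

test_that("generation is deterministic for a fixed seed and errors on tiny images", {
  d <- screen_design(1, 0, n_replicates = 1, n_fields = 1,
                     cells_per_field = c(20L, 30L), image_size = c(256L, 256L))
  tr <- sim_truth(d, seed = 1)
  g1 <- generate_condition_image(d, tr, "P01", "deletion", 1, 1, seed = 7)
  g2 <- generate_condition_image(d, tr, "P01", "deletion", 1, 1, seed = 7)
  expect_identical(g1$pixels, g2$pixels)
  expect_identical(g1$mask, g2$mask)
  d_small <- screen_design(1, 0, n_replicates = 1, n_fields = 1,
                           cells_per_field = c(5L, 5L), image_size = c(24L, 24L))
  expect_error(generate_condition_image(d_small, tr, "P01", "wt", 1, 1, seed = 1),
               "too small")
})

test_that("redistributed labels are conserved and controls carry no effects", {
  d <- screen_design(5, 3)
  tr <- sim_truth(d, seed = 2)
  expect_equal(sum(tr$label_redistributed),
               sum(tr$effect_abundance != 1 | tr$effect_relocalization > 0))
  ctrl <- tr[tr$is_control, ]
  expect_true(all(ctrl$effect_abundance == 1 & ctrl$effect_relocalization == 0))
  expect_false(any(ctrl$label_redistributed))
  expect_true(all(tr$effect_abundance > 0))
  # every protein appears exactly once
  expect_equal(anyDuplicated(tr$protein), 0L)
})

test_that("planted network association raises shared-interactor counts of redistributed pairs", {
  d <- screen_design(10, 2)
  tr <- sim_truth(d, seed = 5)
  nets <- generate_networks(tr, planted_association = TRUE, seed = 5)
  expect_true(all(c("epsilon", "p") %in% names(nets$gi)))
  pairs_tbl <- dplyr::transmute(d$pairs, pair_id = pair_id,
                                gene_a = protein_a, gene_b = protein_b)
  sh <- shared_interactors(filter_ppi_edges(nets$ppi), pairs_tbl)
  redis <- vapply(sh$pair_id, function(p) any(tr$label_redistributed[tr$pair_id == p]), TRUE)
  expect_gt(mean(sh$shared_n[redis]), mean(sh$shared_n[!redis]))
  # within-pair GI edges of redistributed pairs pass the stringent rule
  gi_pairs <- nets$gi[nets$gi$gene_a %in% tr$protein & nets$gi$gene_b %in% tr$protein, ]
  strin <- gi_subset(gi_pairs, "stringent")
  expect_gt(nrow(strin), 0)
})

test_that("without planted association shared-interactor counts are label-independent", {
  set.seed(41)
  ps <- replicate(30, {
    seed <- sample.int(1e6, 1)
    d <- screen_design(12, 0)
    tr <- sim_truth(d, seed = seed)
    # with the association off, any labeling must be unrelated to the counts
    tr$label_redistributed <- tr$pair_id %in% sprintf("pair%02d", 1:6)
    nets <- generate_networks(tr, planted_association = FALSE, seed = seed,
                              base_degree = 15)
    pairs_tbl <- dplyr::transmute(d$pairs, pair_id = pair_id,
                                  gene_a = protein_a, gene_b = protein_b)
    sh <- shared_interactors(nets$ppi, pairs_tbl)
    redis <- vapply(sh$pair_id, function(p) any(tr$label_redistributed[tr$pair_id == p]), TRUE)
    suppressWarnings(wilcox.test(sh$shared_n[redis], sh$shared_n[!redis])$p.value)
  })
  ps <- ps[is.finite(ps)]
  # null p-values should not pile up near zero
  expect_gt(mean(ps > 0.05), 0.6)
})

test_that("planted association is detected by the downstream group comparison", {
  set.seed(99)
  hits <- vapply(1:60, function(i) {
    seed <- sample.int(1e6, 1)
    d <- screen_design(20, 0)
    tr <- sim_truth(d, responsive = "first", seed = seed)
    # make half the pairs null so the comparison has two groups
    tr$label_redistributed[tr$pair_id %in% sprintf("pair%02d", 11:20)] <- FALSE
    nets <- generate_networks(tr, planted_association = TRUE, seed = seed)
    pairs_tbl <- dplyr::transmute(d$pairs, pair_id = pair_id,
                                  gene_a = protein_a, gene_b = protein_b)
    sh <- shared_interactors(filter_ppi_edges(nets$ppi), pairs_tbl)
    sh$redis <- ifelse(vapply(sh$pair_id,
      function(p) any(tr$label_redistributed[tr$pair_id == p]), TRUE), "yes", "no")
    res <- group_compare(sh, "shared_n", "redis")
    !is.na(res$p) && res$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
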