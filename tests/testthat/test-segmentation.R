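test_that("soft-target encoding matches its definition on constructed shapes", {
  # large square: background exactly 0, pixels >= 20 px deep exactly 1
  mask <- matrix(0L, 60, 60)
  mask[6:55, 6:55] <- 1L
  tgt <- encode_target(mask)
  expect_true(all(tgt[mask == 0] == 0))
  expect_equal(tgt[30, 30], 1.0)          # >= 20 px from any background
  # border pixel of the eroded stencil: binary term + 1px scaled distance
  expect_equal(tgt[7, 30], 0.8 + 0.2 * (1 / 20))
  expect_true(all(tgt[tgt > 0] >= 0.8))
  # empty mask is not an error
  expect_equal(encode_target(matrix(0L, 5, 5)), matrix(0, 5, 5))
  expect_error(encode_target(mask, clip = 0), "clip")
  expect_error(encode_target(mask, w = 1), "w must")
})

test_that("soft-target encoding agrees with a brute-force oracle on a random mask", {
  set.seed(11)
  mask <- matrix(0L, 18, 18)
  mask[3:9, 3:10] <- 1L
  mask[11:16, 8:15] <- 2L
  mask[4:7, 13:16] <- 3L
  tgt <- encode_target(mask, clip = 4, w = 0.8)
  # oracle: erosion and exact Euclidean distance by exhaustive search
  nr <- nrow(mask); nc <- ncol(mask)
  er <- matrix(0L, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    l <- mask[r, c]
    if (l == 0) next
    nb <- c(if (r > 1) mask[r - 1, c] else l, if (r < nr) mask[r + 1, c] else l,
            if (c > 1) mask[r, c - 1] else l, if (c < nc) mask[r, c + 1] else l)
    if (all(nb == l)) er[r, c] <- l
  }
  bgpos <- which(er == 0, arr.ind = TRUE)
  oracle <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    if (er[r, c] == 0) next
    dmin <- sqrt(min((bgpos[, 1] - r)^2 + (bgpos[, 2] - c)^2))
    oracle[r, c] <- 0.8 + 0.2 * min(dmin, 4) / 4
  }
  expect_equal(tgt, oracle, tolerance = 1e-12)
})

test_that("background estimation is the per-pixel median", {
  im <- matrix(runif(25), 5, 5)
  expect_equal(estimate_background(list(im, im, im)), im)
  a <- matrix(1, 2, 2); b <- matrix(2, 2, 2); c <- matrix(9, 2, 2)
  expect_equal(estimate_background(list(a, b, c)), matrix(2, 2, 2))
  expect_error(estimate_background(list()), "empty")
  expect_error(estimate_background(list(a, matrix(0, 3, 3))), "shape mismatch")
  # subtraction clips negatives at zero
  expect_equal(subtract_background(a, b), matrix(0, 2, 2))
})

test_that("image normalization standardizes the log-transformed image", {
  expect_warning(out <- normalize_image(matrix(0, 4, 4)), "constant")
  expect_null(out)
  set.seed(2)
  im <- matrix(rexp(10000, 1 / 200), 100, 100)
  nrm <- normalize_image(im)
  expect_lt(abs(mean(nrm$pixels)), 1e-6)
  expect_lt(abs(sd(as.numeric(nrm$pixels)) - 1), 1e-6)
  # log base e with pseudocount: a pixel of exp(1) - 1 contributes x' = 1
  im2 <- matrix(c(exp(1) - 1, 0, 0, 0), 2, 2)
  nrm2 <- normalize_image(im2)
  expect_equal(nrm2$mu, mean(c(1, 0, 0, 0)))
  expect_error(normalize_image(matrix(-1, 2, 2)), "nonnegative")
})

test_that("probability prediction respects shape and range contracts", {
  seg <- train_segmenter(list(matrix(rnorm(96 * 96), 96, 96)),
                         list(matrix(0.5, 96, 96)),
                         seg_config(epochs = 1L, batch_size = 2L), seed = 1)
  p <- predict_probability(seg, matrix(rnorm(100 * 100), 100, 100))
  expect_equal(dim(p), c(100L, 100L))   # reflection-padded to 128 internally
  expect_true(all(p >= 0 & p <= 1))
  expect_error(train_segmenter(list(matrix(0, 4, 4)), list(), seg_config()),
               "paired")
  expect_error(seg_config(crop_size = 100), "divisible by 32")
})

test_that("a desk-scale training run separates cells from background", {
  d <- screen_design(2, 0, n_replicates = 1, n_fields = 2,
                     cells_per_field = c(40L, 60L), image_size = c(320L, 320L))
  tr <- sim_truth(d, seed = 4)
  bg <- matrix(40, 320, 320)
  mk <- function(p, f) {
    g <- generate_condition_image(d, tr, p, "wt", 1, f, seed = 4)
    list(nrm = normalize_image(subtract_background(g$pixels, bg))$pixels,
         tgt = encode_target(g$mask), mask = g$mask, n = g$meta$n_cells)
  }
  train <- list(mk("P01", 1), mk("P03", 1))
  seg <- train_segmenter(lapply(train, `[[`, "nrm"), lapply(train, `[[`, "tgt"),
                         seg_config(), seed = 4)
  # training loss decreases overall
  expect_lt(mean(tail(seg$loss, 3)), mean(head(seg$loss, 3)))
  held <- mk("P02", 2)
  p <- as.numeric(predict_probability(seg, held$nrm))
  y <- as.numeric(held$mask > 0)
  r <- rank(p)
  auc <- (sum(r[y == 1]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(y == 0))
  expect_gt(auc, 0.95)
  # end-to-end instance recovery within 10 percent of ground truth
  found <- max(instances_from_probability(predict_probability(seg, held$nrm)))
  expect_lt(abs(found - held$n) / held$n, 0.10)
})

test_that("watershed splits two bright bumps separated by a valley into two instances", {
  expect_equal(max(instances_from_probability(matrix(0, 50, 50))), 0)
  m <- two_bump_map()
  inst <- instances_from_probability(m, min_area = 100, max_area = 1e5)
  expect_equal(max(inst), 2L)
  # the two regions partition the seeded part of the boundary foreground
  expect_true(all(inst[m < 0.5] == 0))
  # brute-force oracle: seed components count equals instance count
  seeds <- paralogshift:::.cc_label(m >= 0.8, 4L)
  expect_equal(max(seeds), 2L)
})

test_that("size filtering removes objects outside the area bounds", {
  m <- matrix(0, 60, 60)
  m[10:19, 10:19] <- 1.0           # 100-px plateau
  expect_equal(max(instances_from_probability(m)), 0L)
  inst <- instances_from_probability(m, min_area = 50, max_area = 8192)
  expect_equal(max(inst), 1L)
  # property: all returned object areas lie in [min_area, max_area]
  big <- matrix(0, 200, 200)
  big[5:195, 5:60] <- 0.95          # area 10736 > max_area, removed
  big[20:50, 100:150] <- 0.9        # area 1581, kept
  inst2 <- instances_from_probability(big)
  areas <- tabulate(inst2[inst2 > 0])
  expect_true(all(areas >= 256 & areas <= 8192))
  expect_equal(max(inst2), 1L)
  expect_error(instances_from_probability(big, seed_thr = 0.4, boundary_thr = 0.5),
               "exceed")
})

test_that("watershed labels are disjoint regions of the boundary foreground", {
  set.seed(8)
  d <- screen_design(1, 0, n_replicates = 1, n_fields = 1,
                     cells_per_field = c(25L, 30L), image_size = c(300L, 300L))
  tr <- sim_truth(d, seed = 8)
  g <- generate_condition_image(d, tr, "P01", "wt", 1, 1, seed = 8)
  prob <- encode_target(g$mask)   # a valid probability surface by construction
  inst <- instances_from_probability(prob)
  expect_true(all(inst[prob < 0.5] == 0))
  areas <- tabulate(inst[inst > 0])
  expect_true(all(areas >= 256 & areas <= 8192))
  labs <- sort(unique(as.integer(inst[inst > 0])))
  expect_equal(labs, seq_along(labs))  # consecutive labels
})
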