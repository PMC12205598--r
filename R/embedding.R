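# 128-dimensional per-cell embeddings. Two interchangeable backends:
#  (a) a small trained classifier whose penultimate 128-unit layer is the
#      embedding (mirrors training a protein classifier on wild-type frames
#      and reading features from the penultimate pooling layer), and
#  (b) a deterministic handcrafted backend: radial-profile, histogram and
#      gradient features mapped into fixed coordinate blocks of the 128-d
#      output by an orthonormal (DCT) transform. Backend (b) involves no
#      training and no randomness, so results are bit-reproducible.

EMBED_DIM <- 128L

#' Deterministic embedding backend
#'
#' @param frame_size Expected frame side length.
#' @return Object of class `cell_embedder` (type `"deterministic"`).
#' @export
deterministic_embedder <- function(frame_size = 64L) {
  structure(list(type = "deterministic", frame_size = as.integer(frame_size)),
            class = "cell_embedder")
}

# orthonormal DCT-II matrix (N x N)
dct_matrix <- function(N) {
  k <- 0:(N - 1)
  M <- sqrt(2 / N) * cos(pi * outer(k, k + 0.5) / N)
  M[1, ] <- sqrt(1 / N)
  M
}

# ring index cache for radial profiles over the central disk (0 outside)
radial_rings <- local({
  cache <- list()
  function(size, n_rings, rmax = size / 2) {
    key <- paste(size, n_rings, rmax)
    if (is.null(cache[[key]])) {
      ctr <- (size + 1) / 2
      d <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
      ring <- floor(d / rmax * n_rings) + 1L
      ring[ring > n_rings] <- 0L
      cache[[key]] <<- as.integer(ring)
    }
    cache[[key]]
  }
})

# Handcrafted feature blocks, computed on the central disk of the frame
# (radius cell_radius px around the centroid) so neighboring cells in
# crowded fields do not leak into a cell's features. The summary block
# carries intensity information: the frame mean (the only shift-equivariant
# coordinate) plus background-referenced contrast quantiles (central-disk
# quantiles minus the frame's 10th percentile, which is background in a
# frame whose cell covers ~10% of the pixels). All shape blocks are computed
# on the per-disk standardized values, making them exactly invariant to
# affine intensity changes — image-level normalization variability therefore
# reaches only the summary block, not the 120 shape coordinates.
fallback_features <- function(frame, cell_radius = 20) {
  size <- nrow(frame)
  v <- as.numeric(frame)
  ring24 <- radial_rings(size, 24L, cell_radius)
  ring16 <- radial_rings(size, 16L, cell_radius)
  disk <- ring24 > 0L
  cv <- v[disk]
  m <- mean(cv); s <- sd(cv)
  # Contrasts are anchored at the frame minimum (in a background-subtracted,
  # log-standardized image the clipped-to-zero background pixels form an
  # exact per-image constant) and scaled by the background median's offset
  # from that anchor. Both anchors are fixed in raw log-intensity units, so
  # the contrasts are invariant to the per-image affine normalization and
  # measure cell brightness on a comparable scale across images.
  lo <- min(v)
  w <- v - lo
  pos <- w[w > 1e-9]
  # background-subtracted images carry an exact atom at zero (clipped
  # negatives); the continuous positive residuals just above it are
  # background noise, whose lower quartile provides a per-image intensity
  # scale in fixed raw units
  bg_spread <- if (length(pos)) max(quantile(pos, 0.25, names = FALSE), 1e-3) else 1
  qs <- quantile(cv, c(0.25, 0.5, 0.75, 0.9, 0.95, 0.99, 1), names = FALSE)
  summary_blk <- c(mean(v), (qs - lo) / bg_spread)         # 8: mean + contrasts
  z <- if (s > 1e-12) (cv - m) / s else cv * 0
  prof_mean <- vapply(split(z, ring24[disk]), mean, 0)     # 24
  hist_blk <- tabulate(pmin(pmax(floor((z + 3) / 0.25) + 1L, 1L), 24L), 24L) /
    length(z)                                              # 24
  prof_sd <- vapply(split(z, ring16[disk]),
                    function(x) if (length(x) > 1) sd(x) else 0, 0)  # 16
  half <- floor(cell_radius)
  ctr <- (size + 1) / 2
  sub <- frame[(ctr - half):(ctr + half), (ctr - half):(ctr + half)]
  subz <- if (s > 1e-12) (sub - m) / s else sub * 0
  dr <- abs(diff(subz)); dc <- abs(t(diff(t(subz))))
  grad_blk <- quantile(c(dr, dc), c(0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99, 1),
                       names = FALSE)                      # 8
  list(summary = summary_blk, prof_mean = unname(prof_mean), hist = hist_blk,
       prof_sd = unname(prof_sd), grad = grad_blk)
}

fallback_embed_one <- function(frame) {
  blk <- fallback_features(frame)
  out <- numeric(EMBED_DIM)
  pos <- 0L
  for (b in blk) {
    n <- length(b)
    out[pos + seq_len(n)] <- as.numeric(dct_matrix(n) %*% b)
    pos <- pos + n
  }
  out
}

#' Embedding-model training configuration
#'
#' @param epochs,batch_size,lr_init,lr_final Optimizer settings (categorical
#'   cross-entropy, minibatch SGD, cosine-annealed learning rate).
#' @param preset `"desk"` (default) or `"full"` (200 epochs, batch 512).
#' @export
embed_config <- function(epochs = 20L, batch_size = 128L, lr_init = 0.1,
                         lr_final = 1e-3, preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (preset == "full") { epochs <- 200L; batch_size <- 512L }
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr_init = lr_init, lr_final = lr_final)
}

# 4x4 mean pooling of a 64x64 frame to a 256-long input vector
pool_frame <- function(frame) {
  n <- nrow(frame) %/% 4L
  a <- array(frame, c(4L, n, 4L, n))
  as.numeric(apply(a, c(2, 4), mean))
}

#' Train the classifier embedding backend
#'
#' Trains a protein classifier on wild-type-background cell frames
#' (categorical cross-entropy; flips as augmentation; cosine-annealed
#' learning rate) and keeps the penultimate 128-unit layer as the embedding.
#' Cells from field 4 form the validation split when a `field` column is
#' present, mirroring the screen's hold-out convention.
#'
#' @param cells Tibble with list-column `frame`, a `protein` label column and
#'   a `background` column; only wild-type-background frames are accepted.
#' @param config An [embed_config()].
#' @param seed Integer seed.
#' @return Object of class `cell_embedder` (type `"classifier"`) with
#'   training history (`val_accuracy`).
#' @export
train_embedder <- function(cells, config = embed_config(), seed = 1L) {
  stopifnot(is.data.frame(cells), "frame" %in% names(cells))
  if ("background" %in% names(cells) && any(cells$background != "wt"))
    stop("embedding classifier is trained on wild-type-background frames only",
         call. = FALSE)
  labels <- factor(cells$protein)
  if (nlevels(labels) < 2) stop("need at least two protein classes", call. = FALSE)
  size <- nrow(cells$frame[[1]])
  X <- t(vapply(cells$frame, pool_frame, numeric((size %/% 4L)^2)))
  # standardize inputs so the optimizer sees unit-scale features
  in_mu <- colMeans(X)
  in_sd <- pmax(apply(X, 2, sd), 1e-8)
  X <- sweep(sweep(X, 2, in_mu), 2, in_sd, "/")
  K <- nlevels(labels)
  Y <- matrix(0, nrow(X), K); Y[cbind(seq_len(nrow(X)), as.integer(labels))] <- 1

  if ("field" %in% names(cells) && any(cells$field == 4L) && !all(cells$field == 4L)) {
    val_idx <- which(cells$field == 4L)
  } else {
    val_idx <- with_stream_seed(derive_seed(seed, "emb-val"),
                                sample.int(nrow(X), max(1L, nrow(X) %/% 4L)))
  }
  tr_idx <- setdiff(seq_len(nrow(X)), val_idx)

  par <- nn_init(c(ncol(X), EMBED_DIM, K), seed = derive_seed(seed, "emb-init"))
  state <- nn_state_init(par)
  steps_per_epoch <- max(1L, length(tr_idx) %/% config$batch_size)
  total <- config$epochs * steps_per_epoch
  val_acc <- numeric(config$epochs)
  with_stream_seed(derive_seed(seed, "emb-train"), {
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      for (bb in seq_len(steps_per_epoch)) {
        step <- step + 1L
        take <- ord[((bb - 1L) * config$batch_size + 1L):min(bb * config$batch_size, length(ord))]
        Xb <- X[take, , drop = FALSE]
        # flip augmentation on the pooled grid
        g <- sqrt(ncol(Xb))
        if (runif(1) < 0.5) Xb <- Xb[, as.numeric(matrix(seq_len(ncol(Xb)), g, g)[g:1, ]), drop = FALSE]
        if (runif(1) < 0.5) Xb <- Xb[, as.numeric(matrix(seq_len(ncol(Xb)), g, g)[, g:1]), drop = FALSE]
        acts <- nn_forward(par, Xb, output = "softmax")
        grad <- nn_backward(par, acts, Y[take, , drop = FALSE])
        lr <- cosine_lr(step, total, config$lr_init, config$lr_final)
        upd <- nn_step(par, grad, state, lr)
        par <- upd$par; state <- upd$state
      }
      pv <- nn_forward(par, X[val_idx, , drop = FALSE], output = "softmax")
      pred <- max.col(pv[[length(pv)]])
      val_acc[ep] <- mean(pred == as.integer(labels)[val_idx])
    }
  })
  structure(list(type = "classifier", par = par, frame_size = size,
                 in_mu = in_mu, in_sd = in_sd,
                 levels = levels(labels), val_accuracy = val_acc,
                 config = config),
            class = "cell_embedder")
}

#' Embed cell frames
#'
#' @param frames List of square frame matrices (all of the embedder's frame
#'   size).
#' @param embedder A `cell_embedder` ([deterministic_embedder()] or
#'   [train_embedder()]).
#' @return Numeric matrix, one 128-long row per frame.
#' @export
embed_frames <- function(frames, embedder = deterministic_embedder()) {
  stopifnot(inherits(embedder, "cell_embedder"))
  if (length(frames) == 0) return(matrix(0, 0, EMBED_DIM))
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != embedder$frame_size || ncol(f) != embedder$frame_size)
      stop("frame shape must be ", embedder$frame_size, "x", embedder$frame_size,
           call. = FALSE)
  if (embedder$type == "deterministic") {
    t(vapply(frames, fallback_embed_one, numeric(EMBED_DIM)))
  } else {
    X <- t(vapply(frames, pool_frame, numeric((embedder$frame_size %/% 4L)^2)))
    X <- sweep(sweep(X, 2, embedder$in_mu), 2, embedder$in_sd, "/")
    acts <- nn_forward(embedder$par, X, output = "softmax")
    acts[[2]]  # penultimate 128-unit layer
  }
}

#' Add embedding columns to a per-cell table
#'
#' @param cells Tibble with a `frame` list-column.
#' @param embedder A `cell_embedder`.
#' @return `cells` with the frame column dropped and 128 feature columns
#'   `f000`-`f127` appended.
#' @export
embed_cells <- function(cells, embedder = deterministic_embedder()) {
  E <- embed_frames(cells$frame, embedder)
  colnames(E) <- feature_cols()
  dplyr::bind_cols(dplyr::select(cells, -"frame"), tibble::as_tibble(E))
}
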