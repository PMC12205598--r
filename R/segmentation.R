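#' Encode an instance mask into a soft segmentation target
#'
#' Each stencil is first eroded with the minimal cross (a pixel becomes
#' background if any of its four neighbours belongs to the background or to a
#' different instance), then the Euclidean distance to the background is
#' computed on the eroded binary map, clipped at `clip` pixels and scaled to
#' `[0, 1]`. The target is the weighted average `w * binary + (1 - w) *
#' scaled distance` on foreground pixels and 0 on background, so stencil
#' borders sit near `w` and object centers approach 1. This steers a
#' segmentation model toward object centers, which makes touching cells
#' separable downstream.
#'
#' @param mask Integer instance mask (0 = background).
#' @param clip Distance clip in pixels.
#' @param w Weight of the binary term, in (0, 1).
#' @return Numeric matrix in `[0, 1]` of the same shape.
#' @export
encode_target <- function(mask, clip = 20, w = 0.8) {
  assert_matrix(mask)
  if (clip <= 0) stop("clip must be positive")
  if (w <= 0 || w >= 1) stop("w must be in (0, 1)")
  if (!any(mask > 0)) return(matrix(0, nrow(mask), ncol(mask)))
  eroded <- erode_cross_instances(mask)
  bin <- eroded > 0
  d <- EBImage::distmap(bin)
  d <- pmin(as.numeric(d), clip) / clip
  out <- ifelse(bin, w + (1 - w) * d, 0)
  matrix(out, nrow(mask), ncol(mask))
}

# Cross (4-neighbour) erosion that respects instance boundaries: a pixel is
# kept only if all four neighbours carry the same label. Out-of-image
# neighbours are treated as same-label so border cells are not eaten away.
erode_cross_instances <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up <- rbind(mask[1, , drop = FALSE], mask[-nr, , drop = FALSE])
  dn <- rbind(mask[-1, , drop = FALSE], mask[nr, , drop = FALSE])
  lf <- cbind(mask[, 1, drop = FALSE], mask[, -nc, drop = FALSE])
  rt <- cbind(mask[, -1, drop = FALSE], mask[, nc, drop = FALSE])
  keep <- mask > 0 & up == mask & dn == mask & lf == mask & rt == mask
  out <- mask
  out[!keep] <- 0L
  out
}

#' Per-pixel median background of an image collection
#'
#' The background reference is the per-coordinate median across all images,
#' capturing uneven illumination and static readout structure.
#'
#' @param images List of numeric matrices of identical shape.
#' @return Matrix of per-pixel medians.
#' @export
estimate_background <- function(images) {
  if (length(images) == 0) stop("empty image collection", call. = FALSE)
  d <- dim(images[[1]])
  for (im in images) if (!identical(dim(im), d)) stop("shape mismatch in image collection")
  n <- length(images)
  if (n == 1) return(images[[1]])
  # chunk over columns to bound memory for large collections
  out <- matrix(0, d[1], d[2])
  chunk <- max(1L, floor(2e6 / (d[1] * n)))
  for (c0 in seq(1, d[2], by = chunk)) {
    cols <- c0:min(c0 + chunk - 1L, d[2])
    arr <- vapply(images, function(im) im[, cols, drop = FALSE],
                  matrix(0, d[1], length(cols)))
    out[, cols] <- apply(arr, c(1, 2), median)
  }
  out
}

#' Subtract a background reference, clipping negatives at zero
#'
#' @param image Numeric matrix.
#' @param background Background reference from [estimate_background()].
#' @return Matrix of the same shape.
#' @export
subtract_background <- function(image, background) {
  assert_same_dim(image, background, "image and background")
  pmax(image - background, 0)
}

#' Log-transform and standardize an image
#'
#' Applies `log(x + 1)` and standardizes the result to mean 0, standard
#' deviation 1. The detected signal range varies over orders of magnitude
#' between proteins; this normalization puts every image on a comparable
#' scale for the segmentation and embedding models.
#'
#' @param image Nonnegative numeric matrix.
#' @return List with `pixels` (standardized matrix), `mu` and `sigma` of the
#'   log-transformed image, or `NULL` (with a warning) for a constant image,
#'   which carries no usable signal and is excluded.
#' @export
normalize_image <- function(image) {
  assert_matrix(image)
  if (any(image < 0)) stop("image must be nonnegative")
  lg <- log(image + 1)
  mu <- mean(lg); sigma <- sd(as.numeric(lg))
  if (!is.finite(sigma) || sigma == 0) {
    warning("constant image (sigma = 0): excluded from normalization")
    return(NULL)
  }
  list(pixels = (lg - mu) / sigma, mu = mu, sigma = sigma)
}

#' Training configuration for the cell-probability model
#'
#' Desk-scale defaults train in seconds on synthetic fixtures; the
#' `full` preset mirrors a large-scale configuration (200 epochs, learning
#' rate annealed from 3e-4 to 1e-7, 256-pixel crops).
#'
#' @param epochs Training epochs.
#' @param batch_size Random crops drawn per epoch (one gradient step per crop;
#'   the pixels of a crop form the minibatch).
#' @param crop_size Side of square training crops; must be divisible by 32.
#' @param lr_init,lr_final Endpoints of the cosine-annealed learning rate.
#' @param scale_range,shift_range Intensity augmentation: each crop is
#'   multiplied by a factor drawn from `scale_range` and shifted by an offset
#'   drawn from `shift_range`.
#' @param hidden Hidden units of the pixel classifier.
#' @param preset `"desk"` or `"full"`.
#' @return List of class `seg_config`. Loss is binary cross-entropy.
#' @export
seg_config <- function(epochs = 40L, batch_size = 24L, crop_size = 64L,
                       lr_init = 0.1, lr_final = 1e-3,
                       scale_range = c(0.5, 2), shift_range = c(-1, 1),
                       hidden = 12L, preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    epochs <- 200L; batch_size <- 32L; crop_size <- 256L
    lr_init <- 3e-4; lr_final <- 1e-7
  }
  if (crop_size %% 32L != 0L) stop("crop_size must be divisible by 32")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 crop_size = as.integer(crop_size), lr_init = lr_init,
                 lr_final = lr_final, scale_range = scale_range,
                 shift_range = shift_range, hidden = as.integer(hidden),
                 loss = "bce"),
            class = "seg_config")
}

# Multiscale per-pixel features of a normalized image: raw intensity,
# Gaussian blurs at increasing sigma, gradient magnitude and a
# difference-of-Gaussians band. Returned as an (npixels x nfeatures) matrix.
segmentation_features <- function(pixels) {
  blur <- function(m, sigma) {
    r <- min(ceiling(3 * sigma), floor((min(dim(m)) - 1) / 2))
    size <- 2 * r + 1
    if (size < 3) return(m)
    k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
    EBImage::filter2(m, k, boundary = "replicate")
  }
  g1 <- blur(pixels, 1); g2 <- blur(pixels, 2)
  g4 <- blur(pixels, 4); g8 <- blur(pixels, 8)
  nr <- nrow(pixels); nc <- ncol(pixels)
  gr <- (rbind(g2[-1, ], g2[nr, ]) - rbind(g2[1, ], g2[-nr, ])) / 2
  gc <- (cbind(g2[, -1], g2[, nc]) - cbind(g2[, 1], g2[, -nc])) / 2
  grad <- sqrt(gr^2 + gc^2)
  cbind(x = as.numeric(pixels), g1 = as.numeric(g1), g2 = as.numeric(g2),
        g4 = as.numeric(g4), g8 = as.numeric(g8), grad = as.numeric(grad),
        dog = as.numeric(g2 - g8))
}

#' Train the cell-probability model
#'
#' Fits a small pixelwise classifier (a one-hidden-layer network on
#' multiscale Gaussian features) against soft targets from [encode_target()],
#' minimizing binary cross-entropy with minibatch SGD and a cosine-annealed
#' learning rate. Crops are augmented with random flips and intensity
#' scale/shift. This is a desk-scale stand-in honoring the same training
#' contract as a full encoder-decoder segmentation network.
#'
#' @param images List of normalized image matrices (see [normalize_image()]).
#' @param targets List of soft-target matrices paired with `images`.
#' @param config A [seg_config()].
#' @param seed Integer seed for initialization and crop sampling.
#' @param validation Optional list with `images` and `targets` for tracking a
#'   validation loss; defaults to the smoothed training loss.
#' @return Object of class `cell_segmenter` with the fitted parameters and a
#'   per-epoch loss history.
#' @export
train_segmenter <- function(images, targets, config = seg_config(), seed = 1L,
                            validation = NULL) {
  if (length(images) != length(targets) || length(images) == 0)
    stop("images and targets must be paired and nonempty", call. = FALSE)
  for (i in seq_along(images)) assert_same_dim(images[[i]], targets[[i]], "image/target pair")
  par <- nn_init(c(7L, config$hidden, 1L), seed = derive_seed(seed, "seg-init"))
  state <- nn_state_init(par)
  cs <- config$crop_size
  total_steps <- config$epochs * config$batch_size
  loss_hist <- numeric(config$epochs)
  with_stream_seed(derive_seed(seed, "seg-train"), {
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      for (bb in seq_len(config$batch_size)) {
        step <- step + 1L
        ii <- sample.int(length(images), 1L)
        im <- images[[ii]]; tg <- targets[[ii]]
        nr <- nrow(im); nc <- ncol(im)
        cr <- min(cs, nr, nc)
        r0 <- sample.int(nr - cr + 1L, 1L); c0 <- sample.int(nc - cr + 1L, 1L)
        imc <- im[r0:(r0 + cr - 1L), c0:(c0 + cr - 1L)]
        tgc <- tg[r0:(r0 + cr - 1L), c0:(c0 + cr - 1L)]
        if (runif(1) < 0.5) { imc <- imc[cr:1, ]; tgc <- tgc[cr:1, ] }
        if (runif(1) < 0.5) { imc <- imc[, cr:1]; tgc <- tgc[, cr:1] }
        imc <- imc * runif(1, config$scale_range[1], config$scale_range[2]) +
          runif(1, config$shift_range[1], config$shift_range[2])
        X <- segmentation_features(imc)
        Y <- matrix(as.numeric(tgc), ncol = 1)
        acts <- nn_forward(par, X, output = "sigmoid")
        ep_loss <- ep_loss + bce_loss(acts[[length(acts)]], Y)
        grad <- nn_backward(par, acts, Y)
        lr <- cosine_lr(step, total_steps, config$lr_init, config$lr_final)
        upd <- nn_step(par, grad, state, lr)
        par <- upd$par; state <- upd$state
      }
      loss_hist[ep] <- if (is.null(validation)) ep_loss / config$batch_size else {
        vloss <- 0
        for (vi in seq_along(validation$images)) {
          pv <- predict_probability(structure(list(par = par), class = "cell_segmenter"),
                                    validation$images[[vi]])
          vloss <- vloss + bce_loss(as.numeric(pv), as.numeric(validation$targets[[vi]]))
        }
        vloss / length(validation$images)
      }
    }
  })
  structure(list(par = par, config = config, loss = loss_hist),
            class = "cell_segmenter")
}

#' Predict a cell-probability map
#'
#' Pads the input by reflection until both dimensions are divisible by 32,
#' computes multiscale features, applies the fitted classifier, and crops the
#' sigmoid output back to the input shape.
#'
#' @param segmenter A [train_segmenter()] model.
#' @param image Normalized image matrix.
#' @return Probability matrix in `[0, 1]`, same shape as `image`.
#' @export
predict_probability <- function(segmenter, image) {
  stopifnot(inherits(segmenter, "cell_segmenter"))
  assert_matrix(image)
  nr <- nrow(image); nc <- ncol(image)
  nr2 <- ceiling(nr / 32) * 32; nc2 <- ceiling(nc / 32) * 32
  pr <- nr2 - nr; pc <- nc2 - nc
  padded <- image
  if (pr > 0 || pc > 0) {
    p <- max(pr, pc)
    padded <- pad_reflect(image, p)
    padded <- padded[seq_len(nr2), seq_len(nc2)]
  }
  X <- segmentation_features(padded)
  acts <- nn_forward(segmenter$par, X, output = "sigmoid")
  prob <- matrix(acts[[length(acts)]], nrow(padded), ncol(padded))
  prob[seq_len(nr), seq_len(nc)]
}

#' Split a probability map into labeled cell instances
#'
#' Connected components of `prob >= seed_thr` seed a watershed (priority
#' flood on the negated probability map) constrained to `prob >=
#' boundary_thr`; boundary-threshold foreground not reachable from any seed
#' is discarded. Objects outside `[min_area, max_area]` pixels are removed
#' and the surviving labels are renumbered consecutively.
#'
#' @param prob Probability matrix in `[0, 1]`.
#' @param seed_thr,boundary_thr Seed and boundary thresholds, in (0, 1) with
#'   `seed_thr > boundary_thr`.
#' @param min_area,max_area Object area bounds in pixels.
#' @return Integer instance mask.
#' @export
instances_from_probability <- function(prob, seed_thr = 0.8, boundary_thr = 0.5,
                                       min_area = 256L, max_area = 8192L) {
  assert_matrix(prob)
  if (!(seed_thr > 0 && seed_thr < 1 && boundary_thr > 0 && boundary_thr < 1))
    stop("thresholds must lie in (0, 1)")
  if (seed_thr <= boundary_thr) stop("seed_thr must exceed boundary_thr")
  seeds <- .cc_label(prob >= seed_thr, 4L)
  lab <- .watershed_flood(prob, seeds, prob >= boundary_thr)
  relabel_filter(lab, min_area, max_area)
}

# Remove objects outside the area bounds and renumber labels consecutively
# (in increasing original-label order).
relabel_filter <- function(lab, min_area, max_area) {
  if (!any(lab > 0)) return(matrix(0L, nrow(lab), ncol(lab)))
  areas <- tabulate(lab)
  keep <- which(areas >= min_area & areas <= max_area)
  map <- integer(length(areas))
  map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0
  out[pos] <- map[lab[pos]]
  out
}
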