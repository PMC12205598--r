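# Shared fixtures built in code.

# filled disk stencil of radius r centered in a (2r+4)^2 matrix
make_disk <- function(r, pad = 2L) {
  n <- 2L * r + 2L * pad + 1L
  ctr <- r + pad + 1L
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  d <= r
}

# random per-cell embedding table for n cells of one protein/background
make_cells <- function(n, protein = "P01", background = "wt", seed = 1,
                       shift = 0) {
  set.seed(seed)
  E <- matrix(rnorm(n * 128), n, 128) + shift
  colnames(E) <- sprintf("f%03d", 0:127)
  dplyr::bind_cols(
    tibble::tibble(cell_id = seq_len(n), protein = protein,
                   background = background),
    tibble::as_tibble(E)
  )
}

# frames rendered from a compartment template, with noise
make_frames <- function(n, compartment, abundance = 300, seed = 1,
                        geometry = list(a = 14, b = 12, theta = 0)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cell <- render_cell(compartment, abundance * exp(rnorm(1, 0, 0.2)),
                        geometry, noise_params = list(gain = 1, read_sd = 2))
    p <- cell$pixels
    out <- matrix(rnorm(64 * 64, 40, 2), 64, 64)
    ctr <- 32 - (nrow(p) - 1) %/% 2
    idx <- ctr:(ctr + nrow(p) - 1)
    out[idx, idx] <- out[idx, idx] + p
    out
  })
}

# probability map with two radial bumps and a connecting valley
two_bump_map <- function(peak = 0.95, valley = 0.6, sep = 44L, radius = 20) {
  nr <- 80L; nc <- sep + 60L
  c1 <- c(40, 30); c2 <- c(40, 30 + sep)
  f <- function(ctr) {
    d <- sqrt(outer((seq_len(nr) - ctr[1])^2, rep(1, nc)) +
              t(outer((seq_len(nc) - ctr[2])^2, rep(1, nr))))
    peak * pmax(1 - (d / (2.2 * radius))^2, 0)
  }
  m <- pmax(f(c1), f(c2))
  # force the straight path between peaks to a valley level
  m[38:42, 30:(30 + sep)] <- pmin(m[38:42, 30:(30 + sep)], valley)
  m
}
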