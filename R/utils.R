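# Internal helpers shared across modules.

# Deterministic 31-bit stream seed from a base seed and a tag string, so every
# image/condition gets its own reproducible RNG stream regardless of the order
# in which images are generated.
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (v in utf8ToInt(tag)) h <- (h * 33 + v) %% 2147483587
  as.integer(h + 1)
}

with_stream_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) stop(name, " must be a numeric matrix", call. = FALSE)
  invisible(x)
}

assert_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) stop(what, " must have identical dimensions", call. = FALSE)
  invisible(NULL)
}

feature_cols <- function(n = 128L) sprintf("f%03d", seq_len(n) - 1L)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Mirror-pad a matrix by `p` pixels on every side (reflection about the border
# pixel, border row not duplicated). Requires p < dim - 1.
pad_reflect <- function(m, p) {
  if (p == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (p > nr - 1 || p > nc - 1) stop("reflection padding wider than image", call. = FALSE)
  ri <- c((p + 1):2, 1:nr, (nr - 1):(nr - p))
  ci <- c((p + 1):2, 1:nc, (nc - 1):(nc - p))
  m[ri, ci]
}
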