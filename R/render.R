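#' Compartment template vocabulary
#'
#' Parametric intensity templates used by the synthetic renderer. Geometry is
#' analytic (disks, annuli, scattered dots inside an elliptical cell), so the
#' expected signal distribution of every compartment is known exactly.
#'
#' @return Character vector of supported compartment names.
#' @export
compartment_names <- function() {
  c("cytoplasm", "nucleus", "ER", "vacuole", "punctae")
}

# Raw (unnormalized) template value at normalized elliptical radius rho
# (0 = center, 1 = membrane) and normalized in-cell coordinates (u, v).
# Punctae positions are drawn from the current RNG stream.
template_values <- function(compartment, rho, u, v) {
  switch(compartment,
    cytoplasm = rep(1, length(rho)),
    nucleus = ifelse(rho <= 0.4, 1, 0.05),
    ER = ifelse(rho >= 0.55 & rho <= 0.85, 1, 0.25),
    vacuole = ifelse(sqrt((u - 0.25)^2 + v^2) <= 0.45, 1, 0.15),
    punctae = {
      val <- rep(0.08, length(rho))
      k <- 5L
      ang <- runif(k, 0, 2 * pi); rad <- sqrt(runif(k, 0, 1)) * 0.7
      for (i in seq_len(k)) {
        d2 <- (u - rad[i] * cos(ang[i]))^2 + (v - rad[i] * sin(ang[i]))^2
        val[d2 <= 0.12^2] <- 1
      }
      val
    },
    stop("unknown compartment: ", compartment, call. = FALSE)
  )
}

#' Render a single synthetic cell
#'
#' Draws one elliptical cell as an intensity patch plus its binary stencil.
#' The compartment pattern is scaled so that the mean intensity over the
#' stencil equals `abundance`; relocalization is modelled by mixing two
#' normalized templates, which leaves the mean abundance unchanged.
#'
#' @param compartment A compartment name, or a named numeric vector of mixing
#'   weights over compartments (weights must sum to 1), e.g.
#'   `c(ER = 0.4, cytoplasm = 0.6)`.
#' @param abundance Mean fluorescence over the cell (arbitrary units; > 0).
#' @param cell_geometry List with semi-axes `a`, `b` (pixels) and orientation
#'   `theta` (radians).
#' @param noise_params Optional list with `gain` (photons per intensity unit)
#'   and `read_sd` for Poisson-plus-Gaussian noise; `NULL` renders noiseless.
#' @return List with `pixels` (patch matrix) and `stencil` (logical matrix of
#'   identical shape, a single 4-connected region).
#' @export
render_cell <- function(compartment, abundance, cell_geometry = list(a = 12, b = 10, theta = 0),
                        noise_params = NULL) {
  if (!is_scalar_number(abundance) || abundance <= 0)
    stop("abundance must be a single strictly positive number", call. = FALSE)
  if (is.character(compartment)) {
    weights <- setNames(1, compartment)
  } else {
    weights <- compartment
    if (is.null(names(weights)) || abs(sum(weights) - 1) > 1e-8)
      stop("compartment weights must be named and sum to 1", call. = FALSE)
  }
  bad <- setdiff(names(weights), compartment_names())
  if (length(bad)) stop("unknown compartment: ", paste(bad, collapse = ", "), call. = FALSE)

  a <- cell_geometry$a; b <- cell_geometry$b
  theta <- cell_geometry$theta %||% 0
  stopifnot(a > 0, b > 0)
  half <- ceiling(max(a, b)) + 1L
  n <- 2L * half + 1L
  rr <- matrix(rep(seq_len(n) - half - 1L, n), n, n)        # row offsets
  cc <- t(rr)                                               # col offsets
  u <- (cos(theta) * rr + sin(theta) * cc) / a
  v <- (-sin(theta) * rr + cos(theta) * cc) / b
  rho <- sqrt(u^2 + v^2)
  stencil <- rho <= 1

  tmpl <- rep(0, n * n)
  for (w in seq_along(weights)) {
    raw <- template_values(names(weights)[w], rho[stencil], u[stencil], v[stencil])
    tmpl[stencil] <- tmpl[stencil] + weights[[w]] * raw / mean(raw)
  }
  pixels <- matrix(tmpl * abundance, n, n)
  if (!is.null(noise_params)) {
    gain <- noise_params$gain %||% 1
    read_sd <- noise_params$read_sd %||% 0
    shot <- rpois(n * n, pmax(pixels, 0) * gain) / gain
    pixels <- matrix(pmax(shot + rnorm(n * n, 0, read_sd), 0), n, n)
  }
  list(pixels = pixels, stencil = stencil)
}
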