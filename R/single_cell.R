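#' Extract per-cell 64x64 frames from an image
#'
#' Every labeled object in the mask is treated as one cell. A square frame is
#' cut around the instance centroid (rounded to the nearest pixel); frames
#' that would extend past the image border are completed by reflection
#' padding.
#'
#' @param image Numeric image matrix (normalized or raw, caller's choice).
#' @param mask Integer instance mask aligned to `image`.
#' @param size Frame side length in pixels.
#' @return Tibble with one row per instance: `cell_id` (the mask label),
#'   `row`, `col` (0-based centroid), `area`, and `frame` (list-column of
#'   `size` x `size` matrices).
#' @export
extract_frames <- function(image, mask, size = 64L) {
  assert_matrix(image); assert_matrix(mask)
  assert_same_dim(image, mask, "image and mask")
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0) {
    return(tibble::tibble(cell_id = integer(), row = numeric(), col = numeric(),
                          area = integer(), frame = list()))
  }
  idx <- which(mask > 0)
  rr <- (idx - 1L) %% nrow(mask) + 1L
  cc <- (idx - 1L) %/% nrow(mask) + 1L
  lv <- mask[idx]
  cen_r <- round(tapply(rr, lv, mean))
  cen_c <- round(tapply(cc, lv, mean))
  area <- tabulate(mask[mask > 0])[labs]
  half <- size %/% 2L
  pad <- half + 1L
  padded <- pad_reflect(image, pad)
  frames <- purrr::map(seq_along(labs), function(i) {
    r0 <- cen_r[[as.character(labs[i])]] + pad - (half - 1L)
    c0 <- cen_c[[as.character(labs[i])]] + pad - (half - 1L)
    padded[r0:(r0 + size - 1L), c0:(c0 + size - 1L)]
  })
  tibble::tibble(cell_id = as.integer(labs),
                 row = as.numeric(cen_r[as.character(labs)]) - 1,
                 col = as.numeric(cen_c[as.character(labs)]) - 1,
                 area = as.integer(area),
                 frame = frames)
}

#' Morphological features of a single cell stencil
#'
#' Standard region properties: area, convex area (pixels covered by the
#' convex hull of the stencil), equivalent diameter (diameter of the circle
#' with the same area), perimeter (count of exposed pixel edges), the
#' equivalent-ellipse descriptors (major/minor axis length, eccentricity,
#' orientation, from second central moments with the 1/12 px digitization
#' correction), solidity (area / convex area) and the Euler number (connected
#' regions minus holes).
#'
#' @param stencil Logical or 0/1 matrix containing a single connected region.
#' @return One-row tibble with columns `area`, `convex_area`,
#'   `equivalent_diameter`, `perimeter`, `eccentricity`, `major_axis_length`,
#'   `minor_axis_length`, `solidity`, `orientation`, `euler_number`.
#' @export
morphology <- function(stencil) {
  if (is.logical(stencil)) stencil <- stencil * 1L
  assert_matrix(stencil)
  fg <- stencil > 0
  area <- sum(fg)
  if (area == 0) stop("empty stencil", call. = FALSE)
  idx <- which(fg)
  r <- (idx - 1L) %% nrow(stencil)   # 0-based
  c <- (idx - 1L) %/% nrow(stencil)

  # central moments with digitization correction
  mr <- mean(r); mc <- mean(c)
  mu20 <- mean((r - mr)^2) + 1 / 12
  mu02 <- mean((c - mc)^2) + 1 / 12
  mu11 <- mean((r - mr) * (c - mc))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  l2 <- max(l2, 1e-12)
  ecc <- sqrt(max(0, 1 - l2 / l1))
  orientation <- 0.5 * atan2(2 * mu11, mu20 - mu02)

  conv_area <- convex_pixel_area(r, c)
  per <- perimeter_edges(fg)
  euler <- euler_number(fg)

  tibble::tibble(
    area = area,
    convex_area = conv_area,
    equivalent_diameter = sqrt(4 * area / pi),
    perimeter = per,
    eccentricity = ecc,
    major_axis_length = 4 * sqrt(l1),
    minor_axis_length = 4 * sqrt(l2),
    solidity = area / conv_area,
    orientation = orientation,
    euler_number = euler
  )
}

#' Morphology table for every instance of a mask
#'
#' @param mask Integer instance mask.
#' @return Tibble with `cell_id` plus the [morphology()] columns, one row per
#'   instance.
#' @export
morphology_table <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  purrr::map_dfr(labs, function(l) {
    dplyr::mutate(morphology(mask == l), cell_id = as.integer(l), .before = 1)
  })
}

# Pixels covered by the convex hull of the stencil's pixel centers: counts
# pixel centers inside or on the hull polygon.
convex_pixel_area <- function(r, c) {
  if (length(r) <= 2) return(length(r))
  pts0 <- cbind(r, c)
  h <- grDevices::chull(pts0)
  hx <- pts0[h, 1]; hy <- pts0[h, 2]
  rr <- seq(min(r), max(r)); cc <- seq(min(c), max(c))
  pts <- cbind(rep(rr, length(cc)), rep(cc, each = length(rr)))
  sum(points_in_polygon(pts[, 1], pts[, 2], hx, hy))
}

# Even-odd ray casting with an on-edge tolerance (points on the hull count
# as inside).
points_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # on-segment test
    d <- abs((xj - xi) * (py - yi) - (yj - yi) * (px - xi))
    seglen2 <- (xj - xi)^2 + (yj - yi)^2
    t <- ((px - xi) * (xj - xi) + (py - yi) * (yj - yi)) / max(seglen2, eps)
    onedge <- onedge | (d <= eps * sqrt(seglen2) + eps & t >= -eps & t <= 1 + eps)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | onedge
}

# Exposed pixel edges: foreground faces adjacent to background or the image
# border.
perimeter_edges <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- fg
  core <- p[2:(nr + 1), 2:(nc + 1)]
  sum(core & !p[1:nr, 2:(nc + 1)]) + sum(core & !p[3:(nr + 2), 2:(nc + 1)]) +
    sum(core & !p[2:(nr + 1), 1:nc]) + sum(core & !p[2:(nr + 1), 3:(nc + 2)])
}

# Euler number = number of 4-connected foreground components minus number of
# holes (8-connected background components not touching the border).
euler_number <- function(fg) {
  ncomp <- max(.cc_label(fg, 4L))
  nr <- nrow(fg); nc <- ncol(fg)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- fg
  bglab <- .cc_label(!p, 8L)
  nholes <- length(setdiff(unique(as.integer(bglab[bglab > 0])), bglab[1, 1]))
  ncomp - nholes
}
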