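# Two-channel (GFP + ER marker) per-cell compartment quantification with
# quantile-based pixel classification and QC filters.

#' Remove cells near the image border
#'
#' Computes the median major-axis length L over all cells and removes every
#' cell whose stencil enters the border band of width L (0-based pixel
#' distance to the nearest border strictly less than L). Cells touching the
#' border are always removed.
#'
#' @param mask Integer instance mask with at least one cell.
#' @return Filtered mask with surviving labels renumbered consecutively.
#' @export
remove_edge_cells <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0) stop("mask holds no cells", call. = FALSE)
  L <- median(vapply(labs, function(l) morphology(mask == l)$major_axis_length, 0))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask > 0)
  r <- (idx - 1L) %% nr; c <- (idx - 1L) %/% nr   # 0-based
  dist_border <- pmin(r, c, nr - 1L - r, nc - 1L - c)
  bad <- unique(mask[idx[dist_border < L]])
  out <- mask
  out[out %in% bad] <- 0L
  relabel_filter(out, 1L, .Machine$integer.max)
}

#' Background-intensity QC of images within replicates
#'
#' Within each replicate, images whose background intensity lies outside
#' `mean +/- k * sd` of the replicate's backgrounds are discarded.
#' Replicates with fewer than three images skip QC with a warning.
#'
#' @param images Tibble with `replicate`, `image` (identifier) and
#'   `background` (per-image background intensity).
#' @param k Multiplier on the standard deviation.
#' @return `images` with a logical `keep` column.
#' @export
background_qc <- function(images, k = 1) {
  stopifnot(all(c("replicate", "image", "background") %in% names(images)))
  images |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3) {
        warning("replicate ", key$replicate,
                " has fewer than 3 images: background QC skipped")
        return(dplyr::mutate(df, keep = TRUE))
      }
      m <- mean(df$background); s <- sd(df$background)
      dplyr::mutate(df, keep = .data$background >= m - k * s &
                          .data$background <= m + k * s)
    }) |>
    dplyr::ungroup()
}

#' Normalized abundance of one cell
#'
#' Median cell-pixel intensity divided by the image background intensity.
#'
#' @param pixels Numeric vector of the cell's pixel intensities.
#' @param background Positive background intensity of the image.
#' @return Scalar normalized abundance.
#' @export
cell_abundance <- function(pixels, background) {
  if (length(pixels) == 0) stop("empty cell", call. = FALSE)
  if (!is_scalar_number(background) || background <= 0)
    stop("background must be a positive scalar", call. = FALSE)
  median(pixels) / background
}

#' Classify a cell's pixels into ER and cytoplasm by marker quantiles
#'
#' Within one cell, marker-channel pixels at or above the 0.975 intensity
#' quantile are ER; pixels below the 0.973 quantile are cytoplasmic; pixels
#' between the two quantiles stay unassigned. Cells smaller than
#' `min_pixels` (quantiles unreliable) or with fewer than `min_er` ER pixels
#' are discarded.
#'
#' @param marker Numeric vector of the cell's marker-channel intensities.
#' @param er_quantile,cyto_quantile Quantile cuts (linear interpolation).
#' @param min_er Minimum ER pixels to keep the cell.
#' @param min_pixels Minimum cell size for meaningful quantiles.
#' @return List with logical vectors `er` and `cyto`, `n_er`, `kept` and a
#'   `reason` when discarded.
#' @export
compartment_masks <- function(marker, er_quantile = 0.975, cyto_quantile = 0.973,
                              min_er = 100L, min_pixels = 200L) {
  n <- length(marker)
  if (n < min_pixels) {
    return(list(er = logical(n), cyto = logical(n), n_er = 0L,
                kept = FALSE, reason = "too_small"))
  }
  q_er <- quantile(marker, er_quantile, names = FALSE)
  q_cy <- quantile(marker, cyto_quantile, names = FALSE)
  er <- marker >= q_er
  cyto <- marker < q_cy
  if (sum(er) < min_er) {
    return(list(er = er, cyto = cyto, n_er = sum(er),
                kept = FALSE, reason = "few_er_pixels"))
  }
  list(er = er, cyto = cyto, n_er = sum(er), kept = TRUE, reason = NA_character_)
}

#' Per-compartment normalized abundance of one cell
#'
#' Median GFP intensity within each compartment mask, divided by the image
#' background intensity. Empty masks give missing values.
#'
#' @param gfp Numeric vector of the cell's GFP-channel intensities.
#' @param masks A [compartment_masks()] result.
#' @param background Positive background intensity.
#' @return Tibble with `norm_abundance_er` and `norm_abundance_cyto`.
#' @export
compartment_abundance <- function(gfp, masks, background) {
  if (!is_scalar_number(background) || background <= 0)
    stop("background must be a positive scalar", call. = FALSE)
  med_or_na <- function(sel) if (any(sel)) median(gfp[sel]) / background else NA_real_
  tibble::tibble(norm_abundance_er = med_or_na(masks$er),
                 norm_abundance_cyto = med_or_na(masks$cyto))
}

#' Quantify all cells of a two-channel image
#'
#' Applies edge-cell removal, classifies every surviving cell's pixels by
#' marker quantiles, and reports whole-cell, ER and cytoplasmic normalized
#' abundances. The image background is the median over non-cell pixels of
#' the GFP channel unless supplied.
#'
#' @param gfp,marker Image matrices (GFP and ER-marker channels).
#' @param mask Integer instance mask aligned to the channels.
#' @param background Optional background intensity; default median over
#'   non-cell GFP pixels.
#' @param drop_edge_cells Apply [remove_edge_cells()] first.
#' @return Tibble with one row per cell: `cell_id`, `n_pixels`, `n_er_pixels`,
#'   `kept`, `reason`, `norm_abundance_cell`, `norm_abundance_er`,
#'   `norm_abundance_cyto`, `background`.
#' @export
quantify_compartments <- function(gfp, marker, mask, background = NULL,
                                  drop_edge_cells = TRUE) {
  assert_same_dim(gfp, marker, "channels"); assert_same_dim(gfp, mask, "channels and mask")
  if (drop_edge_cells && any(mask > 0)) mask <- remove_edge_cells(mask)
  if (is.null(background)) background <- median(gfp[mask == 0])
  labs <- sort(unique(mask[mask > 0]))
  purrr::map_dfr(labs, function(l) {
    sel <- mask == l
    cm <- compartment_masks(marker[sel])
    ab <- compartment_abundance(gfp[sel], cm, background)
    tibble::tibble(cell_id = as.integer(l), n_pixels = sum(sel),
                   n_er_pixels = cm$n_er, kept = cm$kept, reason = cm$reason,
                   norm_abundance_cell = cell_abundance(gfp[sel], background),
                   norm_abundance_er = ifelse(cm$kept, ab$norm_abundance_er, NA_real_),
                   norm_abundance_cyto = ifelse(cm$kept, ab$norm_abundance_cyto, NA_real_),
                   background = background)
  })
}

#' Compare per-cell compartment abundances between strains
#'
#' Two-sided Mann-Whitney U test on kept cells, per compartment.
#'
#' @param records Tibble of [quantify_compartments()] rows with a `strain`
#'   column holding exactly two levels.
#' @return Tibble: `compartment`, `n_a`, `n_b`, `median_a`, `median_b`, `p`.
#' @export
compare_compartment_groups <- function(records) {
  stopifnot("strain" %in% names(records))
  kept <- dplyr::filter(records, .data$kept)
  lev <- sort(unique(kept$strain))
  stopifnot(length(lev) == 2)
  purrr::map_dfr(c(cell = "norm_abundance_cell", er = "norm_abundance_er",
                   cyto = "norm_abundance_cyto"), .id = "compartment",
                 function(col) {
    xa <- kept[[col]][kept$strain == lev[1]]
    xb <- kept[[col]][kept$strain == lev[2]]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    tibble::tibble(n_a = length(xa), n_b = length(xb),
                   median_a = median(xa), median_b = median(xb),
                   p = suppressWarnings(wilcox.test(xa, xb)$p.value))
  })
}

#' Per-strain summary of compartment abundances with 95% confidence intervals
#'
#' Means and t-based 95% confidence intervals of the kept cells' normalized
#' abundances, per strain and compartment.
#'
#' @param records [quantify_compartments()] rows with a `strain` column.
#' @return Tibble: `strain`, `compartment`, `n`, `mean`, `ci_lo`, `ci_hi`.
#' @export
compartment_strain_summary <- function(records) {
  stopifnot("strain" %in% names(records))
  kept <- dplyr::filter(records, .data$kept)
  cols <- c(cell = "norm_abundance_cell", er = "norm_abundance_er",
            cyto = "norm_abundance_cyto")
  purrr::map_dfr(names(cols), function(cp) {
    kept |>
      dplyr::group_by(.data$strain) |>
      dplyr::summarise(compartment = cp,
                       n = sum(!is.na(.data[[cols[[cp]]]])),
                       mean = mean(.data[[cols[[cp]]]], na.rm = TRUE),
                       se = sd(.data[[cols[[cp]]]], na.rm = TRUE) / sqrt(.data$n),
                       .groups = "drop") |>
      dplyr::mutate(ci_lo = .data$mean - stats::qt(0.975, .data$n - 1) * .data$se,
                    ci_hi = .data$mean + stats::qt(0.975, .data$n - 1) * .data$se) |>
      dplyr::select(-"se")
  })
}

#' Simulate a two-channel validation experiment
#'
#' Renders large elliptical cells with a GFP channel (uniform cytoplasmic
#' signal, optionally ER-enriched) and an ER-marker channel whose planted
#' bright ring occupies roughly `ring_fraction` of each cell, over several
#' images per strain and replicate. Ground truth (the ring pixels) is
#' returned for recall checks.
#'
#' @param n_cells_per_strain Cells per strain (split over
#'   `n_replicates * images_per_replicate` images).
#' @param gfp_effect Multiplicative GFP abundance factor of the second
#'   strain (e.g. 2 for a planted doubling).
#' @param er_enrichment GFP enrichment factor inside the ER ring.
#' @param ring_fraction Fraction of cell pixels occupied by the ring.
#' @param n_replicates,images_per_replicate Imaging layout.
#' @param image_size Image side (pixels).
#' @param seed Integer seed.
#' @param noise List with `offset`, `gain`, `read_sd` (as [screen_noise()],
#'   no touching clumps).
#' @return List with `images` (tibble: strain, replicate, image plus
#'   list-columns `gfp`, `marker`, `mask`, `ring`) and `truth` (per-strain
#'   parameters). Cells are placed away from the border band removed by
#'   [remove_edge_cells()], so edge filtering does not dominate the yield.
#' @export
simulate_two_channel <- function(n_cells_per_strain = 60L, gfp_effect = 2,
                                 er_enrichment = 1.5, ring_fraction = 0.05,
                                 n_replicates = 3L, images_per_replicate = 4L,
                                 image_size = 640L, seed = 1L,
                                 noise = list(offset = 40, gain = 1, read_sd = 2)) {
  strains <- c("wt", "deletion")
  n_img <- n_replicates * images_per_replicate
  per_img <- ceiling(n_cells_per_strain / n_img)
  rho_out <- 0.93
  rho_in <- sqrt(rho_out^2 - ring_fraction)
  rows <- list()
  for (s in seq_along(strains)) {
    abundance <- 60 * if (strains[s] == "deletion") gfp_effect else 1
    for (rep in seq_len(n_replicates)) for (im in seq_len(images_per_replicate)) {
      rows[[length(rows) + 1L]] <- with_stream_seed(
        derive_seed(seed, "2ch", strains[s], rep, im), {
        nr <- image_size
        gfp <- matrix(noise$offset, nr, nr)
        marker <- matrix(noise$offset, nr, nr)
        mask <- matrix(0L, nr, nr)
        ring <- matrix(FALSE, nr, nr)
        centers <- matrix(NA_real_, per_img, 2)
        a <- runif(per_img, 38, 44); b <- a * runif(per_img, 0.88, 1)
        margin <- ceiling(3.2 * max(a))  # clear of the edge-removal band
        if (2 * margin >= nr) stop("image too small for requested cells")
        for (i in seq_len(per_img)) {
          for (att in 1:300) {
            cand <- runif(2, margin, nr - margin)
            if (i == 1) break
            dd <- sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - cand)^2))
            if (all(dd >= a[seq_len(i - 1)] + a[i] + 2)) break
            cand <- NULL
          }
          if (is.null(cand)) stop("image too small for requested cells")
          centers[i, ] <- round(cand)
          theta <- runif(1, 0, pi)
          half <- ceiling(max(a[i], b[i])) + 1L
          n <- 2L * half + 1L
          rr <- matrix(rep(seq_len(n) - half - 1L, n), n, n); cc <- t(rr)
          u <- (cos(theta) * rr + sin(theta) * cc) / a[i]
          v <- (-sin(theta) * rr + cos(theta) * cc) / b[i]
          rho <- sqrt(u^2 + v^2)
          sten <- rho <= 1
          ring_i <- sten & rho >= rho_in & rho <= rho_out
          gfp_cell <- ifelse(sten, abundance * ifelse(ring_i, er_enrichment, 1), 0)
          marker_cell <- ifelse(sten, 30 * ifelse(ring_i, 6, 1), 0)
          ri <- (centers[i, 1] - half):(centers[i, 1] + half)
          ci <- (centers[i, 2] - half):(centers[i, 2] + half)
          gfp[ri, ci] <- gfp[ri, ci] + gfp_cell
          marker[ri, ci] <- marker[ri, ci] + marker_cell
          sub <- mask[ri, ci]; sub[sten & sub == 0L] <- i; mask[ri, ci] <- sub
          rg <- ring[ri, ci]; rg[ring_i] <- TRUE; ring[ri, ci] <- rg
        }
        addnoise <- function(mt) {
          out <- rpois(length(mt), pmax(mt, 0) * noise$gain) / noise$gain
          matrix(pmax(out + rnorm(length(mt), 0, noise$read_sd), 0), nrow(mt), ncol(mt))
        }
        tibble::tibble(strain = strains[s], replicate = rep, image = im,
                       gfp = list(addnoise(gfp)), marker = list(addnoise(marker)),
                       mask = list(mask), ring = list(ring))
      })
    }
  }
  list(images = dplyr::bind_rows(rows),
       truth = tibble::tibble(strain = strains,
                              gfp_abundance = 60 * c(1, gfp_effect),
                              ring_fraction = ring_fraction))
}
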