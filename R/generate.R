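#' Generate one synthetic field image for a condition
#'
#' Renders an image of non-overlapping elliptical cells (with a configurable
#' fraction of touching clumps to exercise instance splitting), applies the
#' planted abundance and relocalization effects for deletion backgrounds, and
#' adds Poisson-plus-Gaussian noise over a constant background offset. The
#' whole process is deterministic given `seed`: every image derives its own
#' RNG stream from the (protein, background, replicate, field) coordinates.
#'
#' @param design A [screen_design()].
#' @param truth A [sim_truth()] table.
#' @param protein,background,replicate,field Condition coordinates.
#' @param seed Integer base seed of the screen.
#' @param noise List with `offset` (background fluorescence), `gain`,
#'   `read_sd`, and `touch_fraction` (fraction of cells placed touching an
#'   existing cell).
#' @return List with `pixels` (intensity matrix), `mask` (integer instance
#'   labels, 0 = background), and `meta` (one-row tibble).
#' @export
generate_condition_image <- function(design, truth, protein, background,
                                     replicate, field, seed = 1L,
                                     noise = screen_noise()) {
  stopifnot(inherits(design, "screen_design"))
  tr <- truth[truth$protein == protein, ]
  if (nrow(tr) != 1) stop("protein not present exactly once in truth: ", protein)
  if (!background %in% c("wt", "deletion")) stop("background must be 'wt' or 'deletion'")
  comps <- unique(c(tr$wt_compartment, tr$target_compartment))
  bad <- setdiff(comps[!is.na(comps)], compartment_names())
  if (length(bad)) stop("unknown compartment: ", paste(bad, collapse = ", "))

  nr <- design$image_size[1]; nc <- design$image_size[2]
  abundance_mean <- tr$abundance_wt
  weights <- setNames(1, tr$wt_compartment)
  if (background == "deletion") {
    abundance_mean <- abundance_mean * tr$effect_abundance
    f <- tr$effect_relocalization
    if (f > 0) weights <- setNames(c(1 - f, f), c(tr$wt_compartment, tr$target_compartment))
  }

  with_stream_seed(derive_seed(seed, protein, background, replicate, field), {
    n_cells <- sample(design$cells_per_field[1]:design$cells_per_field[2], 1L)
    a <- runif(n_cells, 12, 15)
    b <- a * runif(n_cells, 0.8, 1)
    theta <- runif(n_cells, 0, pi)
    r_eff <- pmax(a, b)
    margin <- ceiling(max(r_eff)) + 2L
    if (2 * margin >= min(nr, nc))
      stop("image too small to place one cell", call. = FALSE)
    centers <- matrix(NA_real_, n_cells, 2)
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      touch <- i > 1 && runif(1) < (noise$touch_fraction %||% 0.15)
      for (attempt in seq_len(300L)) {
        if (touch) {
          j <- sample.int(i - 1L, 1L)
          ang <- runif(1, 0, 2 * pi)
          d <- r_eff[i] + r_eff[j] - 1
          cand <- centers[j, ] + d * c(cos(ang), sin(ang))
        } else {
          cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
        }
        if (cand[1] < margin || cand[1] > nr - margin ||
            cand[2] < margin || cand[2] > nc - margin) next
        if (i > 1) {
          prev <- seq_len(i - 1L)
          dd <- sqrt(colSums((t(centers[prev, , drop = FALSE]) - cand)^2))
          lim <- r_eff[prev] + r_eff[i] + 2
          if (touch) {
            # the chosen partner is allowed to touch; all others must clear
            if (dd[j] < 2 || any(dd[-j] < lim[-j])) next
          } else if (any(dd < lim)) next
        }
        centers[i, ] <- round(cand)
        placed <- TRUE
        break
      }
      if (!placed) stop("image too small to place requested cells", call. = FALSE)
    }

    abund <- rlnorm(n_cells, log(abundance_mean), 0.2)
    pixels <- matrix(noise$offset %||% 40, nr, nc)
    mask <- matrix(0L, nr, nc)
    for (i in seq_len(n_cells)) {
      cell <- render_cell(weights, abund[i],
                          list(a = a[i], b = b[i], theta = theta[i]))
      half <- (nrow(cell$pixels) - 1L) / 2L
      ri <- (centers[i, 1] - half):(centers[i, 1] + half)
      ci <- (centers[i, 2] - half):(centers[i, 2] + half)
      pixels[ri, ci] <- pixels[ri, ci] + cell$pixels
      sub <- mask[ri, ci]
      sub[cell$stencil & sub == 0L] <- i
      mask[ri, ci] <- sub
    }
    gain <- noise$gain %||% 1
    read_sd <- noise$read_sd %||% 2
    if (gain > 0) pixels <- matrix(rpois(nr * nc, pmax(pixels, 0) * gain) / gain, nr, nc)
    pixels <- matrix(pmax(pixels + rnorm(nr * nc, 0, read_sd), 0), nr, nc)
    list(pixels = pixels, mask = mask,
         meta = tibble::tibble(protein = protein, background = background,
                               replicate = as.integer(replicate),
                               field = as.integer(field), n_cells = n_cells))
  })
}

#' Default noise model for the synthetic screen
#'
#' @param offset Constant background fluorescence added to every pixel.
#' @param gain Photons per intensity unit for the Poisson shot-noise term
#'   (0 disables shot noise).
#' @param read_sd Standard deviation of Gaussian readout noise.
#' @param touch_fraction Fraction of cells placed in touching clumps.
#' @export
screen_noise <- function(offset = 40, gain = 1, read_sd = 2, touch_fraction = 0.15) {
  list(offset = offset, gain = gain, read_sd = read_sd, touch_fraction = touch_fraction)
}

#' Generate a full synthetic screen in memory
#'
#' Runs [generate_condition_image()] for every condition in the design.
#' Intended for small fixtures; large screens should be generated per
#' condition inside [run_pipeline()] to bound memory.
#'
#' @inheritParams generate_condition_image
#' @return Object of class `synthetic_screen`: list with `images` (list of
#'   per-image lists), `truth`, `design`, `seed`.
#' @export
generate_screen <- function(design, truth, seed = 1L, noise = screen_noise()) {
  conds <- screen_conditions(design)
  images <- purrr::pmap(conds, function(protein, background, replicate, field) {
    generate_condition_image(design, truth, protein, background, replicate,
                             field, seed = seed, noise = noise)
  })
  structure(list(images = images, truth = truth, design = design, seed = seed),
            class = "synthetic_screen")
}

#' Generate synthetic interaction-network tables for a screen
#'
#' Builds protein-protein interaction (PPI) edges, genetic interaction (GI)
#' edges with interaction score epsilon and p-value, and per-protein
#' localization annotations. When `planted_association` is on, members of
#' redistributed pairs receive extra shared interactors, a strongly negative
#' within-pair epsilon, and private interactors enriched in the partner's
#' compartment — giving downstream association tests a known positive.
#'
#' @param truth A [sim_truth()] table.
#' @param planted_association Logical; plant the network signal or not.
#' @param seed Integer seed.
#' @param n_interactors Size of the background interactor pool.
#' @param base_degree Mean baseline degree per protein.
#' @param shared_extra Shared interactors added to redistributed pairs.
#' @return List of tibbles `ppi` (`gene_a`, `gene_b`, `system_type`,
#'   `throughput`, `study_id`), `gi` (`gene_a`, `gene_b`, `epsilon`, `p`) and
#'   `localizations` (`protein`, `compartments` semicolon-joined).
#' @export
generate_networks <- function(truth, planted_association = TRUE, seed = 1L,
                              n_interactors = 200L, base_degree = 6,
                              shared_extra = 6L) {
  stopifnot(base_degree > 0, n_interactors > 10)
  pool <- sprintf("X%03d", seq_len(n_interactors))
  comps <- compartment_names()
  with_stream_seed(derive_seed(seed, "networks"), {
    ppi <- list(); gi <- list()
    loc <- setNames(sample(comps, n_interactors, replace = TRUE), pool)
    neigh <- list()
    for (p in truth$protein) {
      k <- max(1L, rpois(1, base_degree))
      neigh[[p]] <- sample(pool, min(k, n_interactors))
    }
    pair_ids <- unique(truth$pair_id)
    for (pid in pair_ids) {
      members <- truth$protein[truth$pair_id == pid]
      if (length(members) != 2) next
      redis <- any(truth$label_redistributed[truth$pair_id == pid])
      if (planted_association && redis) {
        shared <- sample(pool, shared_extra)
        neigh[[members[1]]] <- unique(c(neigh[[members[1]]], shared))
        neigh[[members[2]]] <- unique(c(neigh[[members[2]]], shared))
        # private interactors in the partner's compartment
        for (m in members) {
          partner <- setdiff(members, m)
          pc <- truth$wt_compartment[truth$protein == partner]
          priv <- setdiff(neigh[[m]], neigh[[partner]])
          relab <- priv[runif(length(priv)) < 0.8]
          loc[relab] <- pc
        }
        gi[[pid]] <- tibble::tibble(gene_a = members[1], gene_b = members[2],
                                    epsilon = rnorm(1, -0.3, 0.05),
                                    p = runif(1, 0, 0.01))
      } else {
        gi[[pid]] <- tibble::tibble(gene_a = members[1], gene_b = members[2],
                                    epsilon = rnorm(1, 0, 0.05),
                                    p = runif(1))
      }
    }
    for (p in names(neigh)) {
      nb <- neigh[[p]]
      n_e <- length(nb)
      ppi[[p]] <- tibble::tibble(
        gene_a = p, gene_b = nb,
        system_type = sample(c("physical", "genetic"), n_e, TRUE, c(0.9, 0.1)),
        throughput = sample(c("high", "low"), n_e, TRUE, c(0.9, 0.1)),
        study_id = sample(sprintf("S%02d", 1:8), n_e, TRUE)
      )
      gi[[paste0("bg_", p)]] <- tibble::tibble(
        gene_a = p, gene_b = sample(pool, min(4L, n_interactors)),
        epsilon = rnorm(4, 0, 0.1), p = runif(4)
      )
    }
    locs <- tibble::tibble(
      protein = c(truth$protein, pool),
      compartments = c(
        purrr::map2_chr(truth$wt_compartment, truth$target_compartment,
                        ~ paste(unique(c(.x, .y[!is.na(.y)])), collapse = ";")),
        unname(loc)
      )
    )
    list(ppi = dplyr::bind_rows(ppi), gi = dplyr::bind_rows(gi), localizations = locs)
  })
}

#' Keep physical, high-throughput PPI edges
#'
#' Standard pre-filter for PPI edge tables: retains edges whose experimental
#' system type is physical and that come from high-throughput studies
#' (optionally restricted to a study whitelist), and drops self-loops.
#'
#' @param edges Tibble with `gene_a`, `gene_b`, `system_type`, `throughput`,
#'   and optionally `study_id`.
#' @param studies Optional character whitelist of study ids.
#' @return Filtered tibble.
#' @export
filter_ppi_edges <- function(edges, studies = NULL) {
  out <- dplyr::filter(edges, .data$system_type == "physical",
                       .data$throughput == "high",
                       .data$gene_a != .data$gene_b)
  if (!is.null(studies)) out <- dplyr::filter(out, .data$study_id %in% studies)
  out
}
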