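#' Lay out a paralog-deletion imaging screen
#'
#' Defines the strain grid of a reciprocal paralog screen: for every pair
#' (A, B), four strains are imaged — A-GFP in the wild-type and in the
#' B-deletion background, and B-GFP in the wild-type and A-deletion
#' background. A set of randomly paired control proteins emulates
#' negative-control strains. The defaults mirror a high-content screen design
#' of three replicates and four imaging fields per condition with fifty to a
#' hundred cells per field.
#'
#' @param n_pairs Number of true paralog pairs.
#' @param n_controls Number of random-pair control pairs (their proteins are
#'   disjoint from the true pairs and carry no planted effect).
#' @param n_replicates Replicates per condition.
#' @param n_fields Imaging fields per condition and replicate.
#' @param cells_per_field Integer range (length 2) of cells per field.
#' @param image_size Image dimensions in pixels, `c(rows, cols)`.
#'
#' @return An object of class `screen_design`: a list with `pairs` (tibble:
#'   `pair_id`, `protein_a`, `protein_b`, `is_control`), `proteins` (tibble:
#'   `protein`, `pair_id`, `partner`, `is_control`) and the sizing parameters.
#' @export
screen_design <- function(n_pairs, n_controls = 0L, n_replicates = 3L,
                          n_fields = 4L, cells_per_field = c(50L, 100L),
                          image_size = c(448L, 448L)) {
  stopifnot(n_pairs >= 0, n_controls >= 0, n_replicates >= 1, n_fields >= 1,
            length(cells_per_field) == 2L, cells_per_field[1] <= cells_per_field[2],
            length(image_size) == 2L)
  ids <- function(prefix, n) if (n > 0) sprintf("%s%02d", prefix, seq_len(n)) else character()
  pair_id <- c(ids("pair", n_pairs), ids("ctrl", n_controls))
  pairs <- tibble::tibble(
    pair_id   = pair_id,
    protein_a = c(ids("P", 2L * n_pairs)[seq_len(n_pairs) * 2L - 1L],
                  ids("C", 2L * n_controls)[seq_len(n_controls) * 2L - 1L]),
    protein_b = c(ids("P", 2L * n_pairs)[seq_len(n_pairs) * 2L],
                  ids("C", 2L * n_controls)[seq_len(n_controls) * 2L]),
    is_control = rep(c(FALSE, TRUE), c(n_pairs, n_controls))
  )
  proteins <- dplyr::bind_rows(
    dplyr::transmute(pairs, protein = .data$protein_a, pair_id = .data$pair_id,
                     partner = .data$protein_b, is_control = .data$is_control),
    dplyr::transmute(pairs, protein = .data$protein_b, pair_id = .data$pair_id,
                     partner = .data$protein_a, is_control = .data$is_control)
  ) |> dplyr::arrange(.data$pair_id, .data$protein)
  structure(list(pairs = pairs, proteins = proteins,
                 n_replicates = as.integer(n_replicates),
                 n_fields = as.integer(n_fields),
                 cells_per_field = as.integer(cells_per_field),
                 image_size = as.integer(image_size)),
            class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat("<screen_design> ", sum(!x$pairs$is_control), " pairs + ",
      sum(x$pairs$is_control), " control pairs; ",
      x$n_replicates, " replicates x ", x$n_fields, " fields, ",
      x$cells_per_field[1], "-", x$cells_per_field[2], " cells/field, ",
      x$image_size[1], "x", x$image_size[2], " px\n", sep = "")
  invisible(x)
}

#' Conditions (images to acquire) implied by a screen design
#'
#' One row per image: protein x background x replicate x field.
#'
#' @param design A [screen_design()].
#' @return Tibble with columns `protein`, `background` (`"wt"` or
#'   `"deletion"`), `replicate`, `field`.
#' @export
screen_conditions <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  tidyr::expand_grid(
    protein = design$proteins$protein,
    background = c("wt", "deletion"),
    replicate = seq_len(design$n_replicates),
    field = seq_len(design$n_fields)
  )
}

#' Ground-truth effect table for a synthetic screen
#'
#' Assigns every protein a wild-type compartment and baseline abundance, and
#' plants the deletion-background effects that downstream stages must recover:
#' a multiplicative abundance factor and/or a relocalization mixing fraction
#' toward a target compartment. Control proteins never carry effects. A
#' protein is labelled redistributed when it carries any non-trivial effect.
#'
#' Default effect sizes model a clearly responsive protein: a 2-fold
#' abundance change and a 0.6 relocalization fraction; the `scenario` cycles
#' effect pairs through abundance-only, relocalization-only and combined
#' responses so that all response scenarios are represented.
#'
#' @param design A [screen_design()].
#' @param effect_abundance Multiplicative abundance factor planted on
#'   abundance-responsive proteins (1 = no change; must be > 0).
#' @param effect_relocalization Mixing fraction in `[0, 1]` of signal moved to
#'   the target compartment for relocalization-responsive proteins.
#' @param abundance_wt Mean baseline fluorescence (arbitrary units).
#' @param responsive Which members of each non-control pair respond:
#'   `"both"`, `"first"`, or `"none"`.
#' @param seed Integer seed controlling compartment assignment.
#' @return Tibble of class `sim_truth` with one row per protein: `protein`,
#'   `pair_id`, `is_control`, `wt_compartment`, `abundance_wt`,
#'   `effect_abundance`, `effect_relocalization`, `target_compartment`,
#'   `label_redistributed`.
#' @export
sim_truth <- function(design, effect_abundance = 2, effect_relocalization = 0.6,
                      abundance_wt = 400, responsive = c("both", "first", "none"),
                      seed = 1L) {
  stopifnot(inherits(design, "screen_design"))
  responsive <- match.arg(responsive)
  if (effect_abundance <= 0) stop("effect_abundance must be strictly positive")
  if (effect_relocalization < 0 || effect_relocalization > 1)
    stop("effect_relocalization must be in [0, 1]")
  comps <- compartment_names()
  pr <- design$proteins
  if (nrow(pr) == 0) {
    return(structure(tibble::tibble(
      protein = character(), pair_id = character(), is_control = logical(),
      wt_compartment = character(), abundance_wt = numeric(),
      effect_abundance = numeric(), effect_relocalization = numeric(),
      target_compartment = character(), label_redistributed = logical()
    ), class = c("sim_truth", "tbl_df", "tbl", "data.frame")))
  }
  with_stream_seed(derive_seed(seed, "truth"), {
    wt_comp <- sample(comps, nrow(pr), replace = TRUE)
    target <- vapply(wt_comp, function(cc) sample(setdiff(comps, cc), 1L), character(1))
    # scenario cycle over effect pairs: abundance / relocalization / both
    scen <- c("abundance", "relocalization", "both")
    pair_scen <- setNames(
      scen[(seq_len(nrow(design$pairs)) - 1L) %% 3L + 1L],
      design$pairs$pair_id
    )
    responds <- !pr$is_control & switch(responsive,
      both = TRUE, first = !duplicated(pr$pair_id), none = FALSE)
    sc <- pair_scen[pr$pair_id]
    ea <- ifelse(responds & sc %in% c("abundance", "both"), effect_abundance, 1)
    er <- ifelse(responds & sc %in% c("relocalization", "both"), effect_relocalization, 0)
    out <- tibble::tibble(
      protein = pr$protein, pair_id = pr$pair_id, is_control = pr$is_control,
      wt_compartment = wt_comp,
      abundance_wt = abundance_wt * rlnorm(nrow(pr), 0, 0.15),
      effect_abundance = ea,
      effect_relocalization = er,
      target_compartment = ifelse(er > 0, target, NA_character_),
      label_redistributed = ea != 1 | er > 0
    )
    class(out) <- c("sim_truth", class(out))
    out
  })
}
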