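#' Compensation/dependency calls per protein
#'
#' Combines a relocalization annotation (an explicit input: visual
#' inspection in a real screen, generator truth in synthetic tests) with the
#' abundance class. An abundance increase marks compensation and a decrease
#' dependency; relocalization to the paralog's wild-type compartment marks
#' compensation, relocalization to a compartment that is neither the
#' protein's own nor its paralog's marks dependency. A relocalized protein
#' whose destination equals its own wild-type compartment is an invalid
#' annotation.
#'
#' @param annotations Tibble with `protein`, `relocalized` (logical),
#'   `destination` (compartment, `NA` unless relocalized),
#'   `own_wt_compartment`, `paralog_wt_compartment`.
#' @param abundance_class Character vector (or tibble with `protein`,
#'   `class`) of abundance classes aligned with `annotations`.
#' @return Tibble with `protein`, `reloc_call`, `abundance_call`, each in
#'   `{"compensation", "dependency", "none"}`.
#' @export
call_direction <- function(annotations, abundance_class) {
  req <- c("protein", "relocalized", "destination", "own_wt_compartment",
           "paralog_wt_compartment")
  stopifnot(all(req %in% names(annotations)))
  if (is.data.frame(abundance_class)) {
    abundance_class <- abundance_class$class[match(annotations$protein,
                                                   abundance_class$protein)]
  }
  if (any(annotations$relocalized & is.na(annotations$destination)))
    stop("relocalized proteins must carry a destination", call. = FALSE)
  if (any(!annotations$relocalized & !is.na(annotations$destination)))
    stop("destination must be missing unless relocalized", call. = FALSE)
  bad <- annotations$relocalized &
    annotations$destination == annotations$own_wt_compartment
  if (any(bad, na.rm = TRUE))
    stop("invalid annotation: relocalization destination equals the protein's own compartment",
         call. = FALSE)
  tibble::tibble(
    protein = annotations$protein,
    reloc_call = dplyr::case_when(
      !annotations$relocalized ~ "none",
      annotations$destination == annotations$paralog_wt_compartment ~ "compensation",
      TRUE ~ "dependency"
    ),
    abundance_call = dplyr::case_when(
      abundance_class == "increase" ~ "compensation",
      abundance_class == "decrease" ~ "dependency",
      TRUE ~ "none"
    )
  )
}

#' Pair-level responsiveness summary
#'
#' Counts pairs in which both members responded (reciprocal), exactly one
#' responded (single), or neither did; optionally summarizes per-axis
#' direction concordance among reciprocal pairs when call columns are
#' present.
#'
#' @param flags Tibble with `protein` and `flag_redistributed` (logical);
#'   may also carry `reloc_call` / `abundance_call`.
#' @param pairs Tibble mapping `protein` to `pair_id` (each protein exactly
#'   once).
#' @return Object of class `pair_summary`: list with `counts` (one-row
#'   tibble: `n_pairs`, `reciprocal`, `single`, `none`,
#'   `n_flagged_proteins`), `per_pair`, and (if calls were supplied)
#'   `concordance`.
#' @export
pair_summary <- function(flags, pairs) {
  stopifnot(all(c("protein", "flag_redistributed") %in% names(flags)),
            all(c("protein", "pair_id") %in% names(pairs)))
  if (anyDuplicated(pairs$protein)) stop("protein mapped to more than one pair")
  unmapped <- setdiff(flags$protein, pairs$protein)
  if (length(unmapped))
    stop("unmapped protein(s): ", paste(unmapped, collapse = ", "), call. = FALSE)
  df <- dplyr::left_join(flags, pairs[, c("protein", "pair_id")], by = "protein")
  per_pair <- df |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::summarise(n_members = dplyr::n(),
                     n_flagged = sum(.data$flag_redistributed), .groups = "drop") |>
    dplyr::mutate(status = dplyr::case_when(
      .data$n_flagged == .data$n_members & .data$n_members > 1 ~ "reciprocal",
      .data$n_flagged >= 1 ~ "single",
      TRUE ~ "none"))
  counts <- tibble::tibble(
    n_pairs = nrow(per_pair),
    reciprocal = sum(per_pair$status == "reciprocal"),
    single = sum(per_pair$status == "single"),
    none = sum(per_pair$status == "none"),
    n_flagged_proteins = sum(df$flag_redistributed)
  )
  out <- list(counts = counts, per_pair = per_pair)
  for (axis in c("reloc_call", "abundance_call")) {
    if (axis %in% names(df)) {
      conc <- df |>
        dplyr::filter(.data[[axis]] != "none") |>
        dplyr::group_by(.data$pair_id) |>
        dplyr::summarise(n = dplyr::n(),
                         concordant = dplyr::n_distinct(.data[[axis]]) == 1,
                         .groups = "drop") |>
        dplyr::filter(.data$n == 2)
      out$concordance[[axis]] <- conc
    }
  }
  structure(out, class = "pair_summary")
}

#' @export
print.pair_summary <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Screen-level summary counts and percentages
#'
#' Headline fractions of a screen: the percentage of proteins flagged as
#' redistributed, and, within the redistributed subset, the percentages that
#' relocalized, changed in abundance, or both. Percentages are rounded
#' half-up to integers.
#'
#' @param roster Tibble with one row per protein: `protein`,
#'   `flag_redistributed` (logical), `abundance_class` (`increase` /
#'   `decrease` / `ns`), `relocalized` (logical).
#' @return One-row tibble with counts and integer percentages; fractions on
#'   the redistributed subset are `NA` when nothing is flagged.
#' @export
screen_summary <- function(roster) {
  stopifnot(all(c("protein", "flag_redistributed", "abundance_class",
                  "relocalized") %in% names(roster)))
  if (nrow(roster) == 0) stop("empty roster", call. = FALSE)
  n <- nrow(roster)
  red <- roster[roster$flag_redistributed, ]
  nr <- nrow(red)
  pct <- function(a, b) if (b > 0) round_half_up(100 * a / b) else NA_real_
  ab <- red$abundance_class %in% c("increase", "decrease")
  tibble::tibble(
    n_proteins = n,
    n_redistributed = nr,
    pct_redistributed = pct(nr, n),
    n_relocalized = sum(red$relocalized),
    pct_relocalized = pct(sum(red$relocalized), nr),
    n_abundance_change = sum(ab),
    pct_abundance_change = pct(sum(ab), nr),
    n_both = sum(red$relocalized & ab),
    pct_both = pct(sum(red$relocalized & ab), nr)
  )
}

#' Export the screen's summary network
#'
#' Builds node and edge tables for a summary-network figure: one node per
#' protein (abundance call, redistribution score, flag) plus one node per
#' destination compartment; one directed edge per relocalized protein from
#' protein to destination, carrying the relocalization call and the score as
#' edge weight.
#'
#' @param calls [call_direction()] output.
#' @param scores [flag_redistributed()] output (protein, score, flag).
#' @param annotations The relocalization annotation table.
#' @return List with `nodes` and `edges` tibbles.
#' @export
export_summary_network <- function(calls, scores, annotations) {
  joined <- calls |>
    dplyr::left_join(dplyr::select(scores, "protein", "score",
                                   "flag_redistributed"), by = "protein") |>
    dplyr::left_join(dplyr::select(annotations, "protein", "relocalized",
                                   "destination"), by = "protein")
  comp_nodes <- unique(joined$destination[!is.na(joined$destination)])
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = joined$protein, type = "protein",
                   abundance_call = joined$abundance_call,
                   score = joined$score,
                   flag_redistributed = joined$flag_redistributed),
    tibble::tibble(node = comp_nodes, type = "compartment",
                   abundance_call = NA_character_, score = NA_real_,
                   flag_redistributed = NA)
  )
  edges <- joined |>
    dplyr::filter(.data$relocalized) |>
    dplyr::transmute(from = .data$protein, to = .data$destination,
                     reloc_call = .data$reloc_call, weight = .data$score)
  list(nodes = nodes, edges = edges)
}

#' Remove quality-flagged pairs from the screen roster
#'
#' Removal is pairwise: both members of a flagged pair leave the roster
#' together.
#'
#' @param pairs Tibble with `pair_id`, `protein_a`, `protein_b`.
#' @param flagged_pairs Character vector of `pair_id`s to remove.
#' @return List with `pairs` (remaining tibble), `n_pairs`, `n_proteins`,
#'   `n_removed_pairs`, `n_removed_proteins`.
#' @export
roster_filter <- function(pairs, flagged_pairs = character()) {
  stopifnot(all(c("pair_id", "protein_a", "protein_b") %in% names(pairs)))
  missing <- setdiff(flagged_pairs, pairs$pair_id)
  if (length(missing))
    stop("flagged pair(s) not in roster: ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- !(pairs$pair_id %in% flagged_pairs)
  out <- pairs[keep, ]
  list(pairs = out,
       n_pairs = nrow(out),
       n_proteins = 2L * nrow(out),
       n_removed_pairs = sum(!keep),
       n_removed_proteins = 2L * sum(!keep))
}
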