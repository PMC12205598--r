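#' Run the full synthetic-screen analysis pipeline
#'
#' Orchestrates all stages in dependency order: screen design and ground
#' truth, background reference, segmenter training, per-image cell
#' extraction and embedding, redistribution scoring with ROC threshold
#' selection, abundance statistics, compensation/dependency calls, and
#' network association. Each stage writes its outputs under
#' `config$out_dir`; with `resume = TRUE`, stages whose outputs exist are
#' skipped. A manifest (config snapshot, seed, output hashes) is written
#' last. Identical configurations and seeds reproduce identical tables.
#'
#' @param config A [pipeline_config()] (or a path to a YAML/JSON config).
#' @return Invisibly, a list with the main result tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, output, fun) {
    paths <- file.path(out, output)
    if (config$resume && all(file.exists(paths))) {
      message("[", name, "] outputs exist, skipped")
      return(NULL)
    }
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  design <- screen_design(config$n_pairs, config$n_controls, config$n_replicates,
                          config$n_fields, config$cells_per_field, config$image_size)
  truth <- sim_truth(design, effect_abundance = config$effect_abundance,
                     effect_relocalization = config$effect_relocalization,
                     seed = config$seed)
  stage("design", c("design.csv", "truth.csv"), function() {
    write_table(design$pairs, file.path(out, "design.csv"))
    write_table(truth, file.path(out, "truth.csv"))
  })

  conds <- screen_conditions(design)
  gen <- function(i) {
    generate_condition_image(design, truth, conds$protein[i], conds$background[i],
                             conds$replicate[i], conds$field[i], seed = config$seed)
  }

  # background reference from a deterministic image subsample
  bg_idx <- with_stream_seed(derive_seed(config$seed, "bg-sample"),
                             sample.int(nrow(conds), min(config$n_background_images,
                                                         nrow(conds))))
  background <- stage("background", "background.tif", function() {
    b <- estimate_background(lapply(bg_idx, function(i) gen(i)$pixels))
    write_image(b, file.path(out, "background.tif"))
    b
  })
  if (is.null(background)) background <- read_image(file.path(out, "background.tif"))

  segmenter <- NULL
  if (config$segmentation == "trained") {
    tr_idx <- with_stream_seed(derive_seed(config$seed, "seg-sample"),
                               sample.int(nrow(conds), min(config$n_train_images,
                                                           nrow(conds))))
    imgs <- list(); tgts <- list()
    for (i in tr_idx) {
      g <- gen(i)
      nrm <- normalize_image(subtract_background(g$pixels, background))
      if (is.null(nrm)) next
      imgs[[length(imgs) + 1L]] <- nrm$pixels
      tgts[[length(tgts) + 1L]] <- encode_target(g$mask)
    }
    segmenter <- train_segmenter(imgs, tgts, seg_config(), seed = config$seed)
  }

  cells_path <- file.path(out, "cells.csv")
  qc_path <- file.path(out, "qc.csv")
  if (!(config$resume && file.exists(cells_path))) {
    embedder <- deterministic_embedder()
    cell_rows <- vector("list", nrow(conds)); qc_rows <- vector("list", nrow(conds))
    for (i in seq_len(nrow(conds))) {
      g <- gen(i)
      raw <- subtract_background(g$pixels, background)
      nrm <- normalize_image(raw)
      if (is.null(nrm)) {
        qc_rows[[i]] <- dplyr::mutate(g$meta, n_cells_detected = NA_integer_,
                                      median_area = NA_real_,
                                      note = "constant image excluded")
        next
      }
      mask <- if (config$segmentation == "truth") {
        relabel_filter(g$mask, 256L, 8192L)
      } else {
        instances_from_probability(predict_probability(segmenter, nrm$pixels))
      }
      fr_norm <- extract_frames(nrm$pixels, mask)
      if (nrow(fr_norm) == 0) {
        qc_rows[[i]] <- dplyr::mutate(g$meta, n_cells_detected = 0L,
                                      median_area = NA_real_, note = "no cells")
        next
      }
      fr_raw <- extract_frames(raw, mask)
      emb <- embed_frames(fr_norm$frame, embedder)
      colnames(emb) <- feature_cols()
      cell_rows[[i]] <- dplyr::bind_cols(
        dplyr::bind_cols(g$meta[rep(1, nrow(fr_norm)),
                                c("protein", "background", "replicate", "field")],
                         dplyr::select(fr_norm, -"frame")),
        tibble::tibble(intensity_mean = vapply(fr_raw$frame, mean, 0)),
        tibble::as_tibble(emb))
      qc_rows[[i]] <- dplyr::mutate(g$meta, n_cells_detected = nrow(fr_norm),
                                    median_area = median(fr_norm$area),
                                    note = NA_character_)
    }
    cells <- dplyr::bind_rows(cell_rows)
    write_table(cells, cells_path)
    write_table(dplyr::bind_rows(qc_rows), qc_path)
  } else {
    cells <- read_table(cells_path)
  }

  scores_path <- file.path(out, "redistribution.csv")
  scores <- redistribution_scores(cells)
  thr <- select_threshold(
    scores$score[scores$protein %in% truth$protein[truth$label_redistributed]],
    scores$score[scores$protein %in% truth$protein[truth$is_control]]
  )
  scores <- flag_redistributed(scores, thr)
  write_table(scores, scores_path)

  ab <- abundance_table(cells)
  write_table(ab, file.path(out, "abundance.csv"))

  partner <- setNames(design$proteins$partner, design$proteins$protein)
  ann <- tibble::tibble(
    protein = truth$protein,
    relocalized = truth$effect_relocalization > 0,
    destination = ifelse(truth$effect_relocalization > 0,
                         truth$target_compartment, NA_character_),
    own_wt_compartment = truth$wt_compartment,
    paralog_wt_compartment = truth$wt_compartment[match(partner[truth$protein],
                                                        truth$protein)]
  )
  calls <- call_direction(ann, dplyr::select(ab, "protein", "class"))
  write_table(calls, file.path(out, "calls.csv"))

  flags <- dplyr::left_join(
    dplyr::select(scores, "protein", "flag_redistributed"),
    calls, by = "protein")
  ps <- pair_summary(flags, design$proteins)
  write_table(ps$per_pair, file.path(out, "pair_summary.csv"))
  roster <- dplyr::left_join(flags, dplyr::select(ann, "protein", "relocalized"),
                             by = "protein") |>
    dplyr::left_join(dplyr::select(ab, "protein", abundance_class = "class"),
                     by = "protein")
  summ <- screen_summary(roster)
  jsonlite::write_json(c(as.list(summ), as.list(ps$counts),
                         list(threshold = thr$threshold, threshold_fpr = thr$fpr,
                              threshold_fnr = thr$fnr)),
                       file.path(out, "screen_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  net <- export_summary_network(calls, scores, ann)
  write_table(net$nodes, file.path(out, "summary_network_nodes.csv"))
  write_table(net$edges, file.path(out, "summary_network_edges.csv"))

  # PCA visualization coordinates per pair
  pca_dir <- file.path(out, "pca")
  dir.create(pca_dir, showWarnings = FALSE)
  for (pid in design$pairs$pair_id) {
    members <- design$proteins$protein[design$proteins$pair_id == pid]
    sub <- dplyr::filter(cells, .data$protein %in% members)
    if (nrow(sub) < 3) next
    pv <- pca_view(sub)
    write_table(pv$scores, file.path(pca_dir, paste0(pid, "_coords.csv")))
  }

  nets <- generate_networks(truth, planted_association = TRUE, seed = config$seed)
  ppi <- filter_ppi_edges(nets$ppi)
  pairs_tbl <- dplyr::transmute(design$pairs, pair_id = .data$pair_id,
                                gene_a = .data$protein_a, gene_b = .data$protein_b)
  feat <- shared_interactors(ppi, pairs_tbl) |> shortest_path_class(graph = ppi)
  per_protein <- dplyr::left_join(design$proteins,
                                  dplyr::select(feat, "pair_id", "bin", "path_class"),
                                  by = "pair_id") |>
    dplyr::left_join(dplyr::select(scores, "protein", "score", "flag_redistributed"),
                     by = "protein")
  net_stats <- group_compare(per_protein, "score", c("bin", "path_class"))
  write_table(net_stats, file.path(out, "network_stats.csv"))

  write_manifest(config, out, c("design.csv", "truth.csv", "background.tif",
                                "cells.csv", "qc.csv", "redistribution.csv",
                                "abundance.csv", "calls.csv", "pair_summary.csv",
                                "screen_summary.json", "network_stats.csv",
                                "summary_network_nodes.csv",
                                "summary_network_edges.csv"))
  invisible(list(design = design, truth = truth, cells = cells, scores = scores,
                 threshold = thr, abundance = ab, calls = calls,
                 pair_summary = ps, screen_summary = summ,
                 network_stats = net_stats))
}
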