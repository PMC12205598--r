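# Format readers/writers, configuration and run manifest.

#' Read a grayscale image (TIFF or PNG)
#'
#' 16-bit TIFF and 8/16-bit PNG images are returned as numeric matrices on
#' the integer intensity scale (0..65535 for 16-bit, 0..255 for 8-bit).
#'
#' @param path File path; format chosen by extension.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    m <- png::readPNG(path, info = TRUE)
    info <- attr(m, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    m <- round(m * (2^depth - 1))
  } else stop("unsupported image format: .", ext, call. = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.numeric(m), nrow(m), ncol(m))
}

#' Write a grayscale image (16-bit TIFF or PNG)
#'
#' @param image Numeric matrix on the integer intensity scale; values are
#'   rounded and clipped to the bit depth.
#' @param path Destination; format chosen by extension.
#' @param bits Bit depth (TIFF always 16; PNG written at 8 bits, enough for
#'   masks with up to 255 labels).
#' @export
write_image <- function(image, path, bits = 16L) {
  assert_matrix(image)
  if (!bits %in% c(8L, 16L)) stop("unsupported bit depth: ", bits, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pmin(pmax(round(image), 0), 65535) / 65535, path,
                    bits.per.sample = 16L)
  } else if (ext == "png") {
    if (bits != 8L) stop("unsupported bit depth: PNG output is 8-bit", call. = FALSE)
    png::writePNG(pmin(pmax(round(image), 0), 255) / 255, path)
  } else stop("unsupported image format: .", ext, call. = FALSE)
  invisible(path)
}

#' Write / read a pipeline table with schema checking
#'
#' CSV dialect: UTF-8, comma separator, header row, `.` decimal mark,
#' missing values as empty fields.
#'
#' @param x Data frame.
#' @param path CSV path.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname write_table
#' @param required Character vector of required column names.
#' @export
read_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("table not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(x))
    if (length(missing))
      stop("table ", basename(path), " lacks required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

#' Pipeline configuration
#'
#' Assembles (or loads from YAML/JSON) the configuration consumed by
#' [run_pipeline()], validating required fields before any computation.
#'
#' @param out_dir Output directory.
#' @param seed Integer base seed for every stochastic stage.
#' @param n_pairs,n_controls,n_replicates,n_fields,cells_per_field,image_size
#'   Screen design parameters (see [screen_design()]).
#' @param effect_abundance,effect_relocalization Planted effect sizes.
#' @param segmentation `"trained"` (train the pixel classifier on generated
#'   annotated images) or `"truth"` (use generator masks directly).
#' @param n_background_images Images sampled for the background reference.
#' @param n_train_images Annotated images for segmenter training.
#' @param resume Skip stages whose outputs already exist.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_pairs = 6L, n_controls = 2L,
                            n_replicates = 3L, n_fields = 4L,
                            cells_per_field = c(50L, 100L),
                            image_size = c(448L, 448L),
                            effect_abundance = 2, effect_relocalization = 0.6,
                            segmentation = c("trained", "truth"),
                            n_background_images = 32L, n_train_images = 12L,
                            resume = FALSE) {
  segmentation <- match.arg(segmentation)
  if (missing(out_dir) || !nzchar(out_dir))
    stop("config lacks required field: out_dir", call. = FALSE)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_pairs = as.integer(n_pairs), n_controls = as.integer(n_controls),
              n_replicates = as.integer(n_replicates), n_fields = as.integer(n_fields),
              cells_per_field = as.integer(cells_per_field),
              image_size = as.integer(image_size),
              effect_abundance = effect_abundance,
              effect_relocalization = effect_relocalization,
              segmentation = segmentation,
              n_background_images = as.integer(n_background_images),
              n_train_images = as.integer(n_train_images),
              resume = isTRUE(resume))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML or JSON configuration file.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (tolower(tools::file_ext(path)) %in% c("yml", "yaml"))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$out_dir)) stop("config lacks required field: out_dir", call. = FALSE)
  do.call(pipeline_config, raw)
}

# Run manifest: config snapshot, seed, package version, output hashes.
write_manifest <- function(cfg, out_dir, outputs) {
  manifest <- list(
    package = "paralogshift",
    version = as.character(utils::packageVersion("paralogshift")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = unclass(cfg),
    outputs = lapply(outputs, function(f) {
      p <- file.path(out_dir, f)
      if (file.exists(p)) list(file = f, md5 = unname(tools::md5sum(p)),
                               bytes = file.size(p))
      else list(file = f, md5 = NA, bytes = NA)
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
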