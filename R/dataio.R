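#' Multi-channel image field
#'
#' @param pixels named list of `H x W` numeric matrices, one per channel,
#'   in native intensity units.
#' @param channels ordered channel role names (defaults to names of
#'   `pixels`).
#' @param image_id identifier string.
#' @return an object of class `image_field`.
#' @export
image_field <- function(pixels, channels = names(pixels), image_id = "") {
  if (!is.list(pixels) || length(pixels) < 1)
    stop_locnet("data", "pixels must be a non-empty list of matrices")
  dims <- vapply(pixels, dim, integer(2))
  if (length(pixels) > 1 && !all(dims == dims[, 1]))
    stop_locnet("data", "all channels must share height and width")
  if (is.null(channels)) channels <- paste0("ch", seq_along(pixels))
  names(pixels) <- channels
  structure(list(pixels = pixels, channels = channels,
                 image_id = image_id),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("<image_field> '%s' %dx%d, channels: %s\n", x$image_id,
              nrow(x$pixels[[1]]), ncol(x$pixels[[1]]),
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Read a TIFF or PNG image into an image field
#'
#' TIFF pages map to channels in file order; PNG files carry a single
#' grayscale channel.  Intensities are preserved without rescaling (a
#' 16-bit image reads back with values up to 65535).  Which plane plays
#' which role (GFP, marker, ...) is supplied by the caller or the run
#' configuration, not inferred from the file.
#'
#' @param path image path (`.tif`, `.tiff`, or `.png`).
#' @param channels expected ordered channel role names; a mismatch with
#'   the number of planes found is a configuration error.  `NULL` accepts
#'   whatever the file holds with generated names.
#' @param image_id identifier; defaults to the file name without
#'   extension.
#' @return an `image_field`.
#' @export
read_image <- function(path, channels = NULL, image_id = NULL) {
  if (!file.exists(path))
    stop_locnet("io", "image file '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  planes <- switch(ext,
    tif = , tiff = read_tiff(path),
    png = list(read_png(path)),
    stop_locnet("io", "unsupported image format '.%s'", ext))
  if (!is.null(channels) && length(channels) != length(planes))
    stop_locnet("config",
                "image '%s' has %d channel(s) but config expects %d (%s)",
                path, length(planes), length(channels),
                paste(channels, collapse = ", "))
  if (is.null(channels)) channels <- paste0("ch", seq_along(planes))
  if (is.null(image_id))
    image_id <- tools::file_path_sans_ext(basename(path))
  image_field(setNames(lapply(planes, function(p) p * 1.0), channels),
              channels = channels, image_id = image_id)
}

#' Write an image field to TIFF (multi-page) or PNG (single channel)
#'
#' @param field an `image_field`.
#' @param path output path; format chosen by extension.
#' @param bits 8 or 16 bits per sample.
#' @return the path, invisibly.
#' @export
write_image <- function(field, path, bits = 16L) {
  stopifnot(inherits(field, "image_field"))
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
      tif = , tiff = write_tiff(field$pixels, path, bits),
      png = {
        if (length(field$pixels) != 1)
          stop_locnet("io", "PNG output supports a single channel")
        write_png(field$pixels[[1]], path, bits)
      },
      stop_locnet("io", "unsupported image format '.%s'", ext))
    TRUE
  }, error = function(e) {
    if (inherits(e, "locnet_error")) stop(e)
    stop_locnet("io", "cannot write '%s': %s", path, conditionMessage(e))
  })
  invisible(path)
}

#' Read a cell coordinate table
#'
#' Delimited text (TSV or CSV, auto-detected) with a header naming at
#' least `image_id`, `x`, `y`; optional `label`, `protein_id`,
#' `condition`, and any further columns are preserved.  Coordinates are
#' 0-based pixel indices of the crop center (`x` = column, `y` = row).
#'
#' @param path table path.
#' @return a data.frame with one row per cell.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path))
    stop_locnet("io", "cell table '%s' does not exist", path)
  dt <- data.table::fread(path, header = TRUE, sep = "auto",
                          data.table = FALSE, colClasses = NULL)
  mandatory <- c("image_id", "x", "y")
  missing_cols <- setdiff(mandatory, names(dt))
  if (length(missing_cols))
    stop_locnet("schema", "cell table '%s' lacks mandatory column(s): %s",
                path, paste(missing_cols, collapse = ", "))
  for (col in c("x", "y")) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad))
        stop_locnet("parse",
                    "non-numeric %s coordinate '%s' in row %d of '%s'",
                    col, v[bad[1]], bad[1], path)
      dt[[col]] <- parsed
    }
  }
  if (nrow(dt) && any(dt$x < 0 | dt$y < 0, na.rm = TRUE))
    stop_locnet("schema", "coordinates must be non-negative in '%s'", path)
  dt
}

#' Write a tabular result as TSV
#'
#' Floats are written at full precision so that a write/read round trip
#' preserves values to within floating-point parsing accuracy.  An empty
#' result set yields a header-only file.
#'
#' @param rows a data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  ok <- tryCatch({
    data.table::fwrite(rows, path, sep = "\t", quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) {
    stop_locnet("io", "cannot write table '%s': %s", path,
                conditionMessage(e))
  })
  invisible(path)
}

#' Read and validate a run configuration (JSON)
#'
#' Known keys: `classes` (class vocabulary), `channels` (ordered channel
#' role names mapping image planes), `crop_size`, `seed`, `out_dir`, plus
#' optional nested `model`, `train`, `transfer`, `simulate`, `screen`
#' blocks passed to the corresponding constructors.  Each subcommand
#' validates only the fields it uses.
#'
#' @param path JSON file path.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_locnet("io", "config file '%s' does not exist", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # nested blocks of uniform scalars simplify to named vectors; keep lists
  for (blk in c("model", "train", "transfer", "simulate", "screen")) {
    if (!is.null(cfg[[blk]])) cfg[[blk]] <- as.list(cfg[[blk]])
  }
  defaults <- list(classes = c("cytoplasm", "nucleus", "nuclear_periphery",
                               "cell_periphery", "punctate_k8", "bud_neck"),
                   channels = c("green", "red"),
                   crop_size = 64L, seed = 1L, out_dir = ".")
  cfg <- modifyList(defaults, cfg)
  if (!is.numeric(cfg$crop_size) || cfg$crop_size <= 0)
    stop_locnet("config", "config field 'crop_size': must be a positive number")
  if (!is.numeric(cfg$seed))
    stop_locnet("config", "config field 'seed': must be numeric")
  if (length(cfg$classes) < 2)
    stop_locnet("config", "config field 'classes': need at least 2 classes")
  class(cfg) <- "run_config"
  cfg
}
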