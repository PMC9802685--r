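# Readers/writers for the tool's file formats: 16-bit grayscale TIFF/PNG
# images, landmark/target CSV tables, JSON configuration.

#' Read a grayscale image (TIFF or PNG)
#'
#' Multi-page TIFFs are returned as a `[y, x, page]` array in page order.
#'
#' @param path File path.
#' @return Numeric matrix in \[0, 1\] (or 3-D array for multi-page TIFF).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      rlang::abort("the png package is required to read PNG files")
    }
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  if (length(pages) == 1) pages[[1]] else simplify2array(pages)
}

#' Write a grayscale image as 16-bit TIFF (or PNG)
#'
#' @param image Matrix in \[0, 1\], or a `[y, x, page]` array for a
#'   multi-page TIFF.
#' @param path Output path; format chosen by extension.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      rlang::abort("the png package is required to write PNG files")
    }
    png::writePNG(clamp01(image), path)
    return(invisible(path))
  }
  if (length(dim(image)) == 3) {
    tiff::writeTIFF(lapply(seq_len(dim(image)[3]), function(i) clamp01(image[, , i])),
                    path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(clamp01(image), path, bits.per.sample = 16L)
  }
  invisible(path)
}

landmark_columns <- c("label", "frame", "stage_x_um", "stage_y_um", "status")

#' Read a landmark table
#'
#' CSV with mandatory columns `label`, `frame` (LM/EM), `stage_x_um`,
#' `stage_y_um`, `status`; duplicate (label, frame) rows are an error.
#'
#' @param path CSV path.
#' @return A `clem_landmark_map` tibble.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(landmark_columns, names(tbl))
  if (length(missing)) {
    rlang::abort(sprintf("landmark file lacks required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tbl[, c("label", "frame")])) {
    rlang::abort("duplicate (label, frame) entries in landmark file")
  }
  structure(tbl, class = c("clem_landmark_map", class(tbl)))
}

#' Write a landmark table
#'
#' @param map Landmark tibble (see [read_landmarks()] for the schema).
#' @param path Output CSV path.
#' @export
write_landmarks <- function(map, path) {
  missing <- setdiff(landmark_columns, names(map))
  if (length(missing)) {
    rlang::abort(sprintf("landmark table lacks required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(map[, c("label", "frame")])) {
    rlang::abort("duplicate (label, frame) entries in landmark table")
  }
  readr::write_csv(tibble::as_tibble(map), path)
  invisible(path)
}

#' Read / write the project configuration
#'
#' JSON with sections mirroring the parameter constructors (`grid_layout`,
#' `lod_params`, `registration_params`, `beam_geometry`, `monitor_config`,
#' `feature_config`, plus `seed`). Unknown top-level keys are rejected.
#'
#' @param path JSON path.
#' @return A named list of parameter objects.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("grid_layout", "lod_params", "registration_params",
             "beam_geometry", "monitor_config", "feature_config", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    rlang::abort(sprintf("unknown configuration key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  build <- function(ctor, args) {
    if (is.null(args)) return(ctor())
    args <- as.list(args)
    do.call(ctor, args[intersect(names(args), names(formals(ctor)))])
  }
  list(grid_layout = build(grid_layout, raw$grid_layout),
       lod_params = build(lod_params, raw$lod_params),
       registration_params = build(registration_params, raw$registration_params),
       beam_geometry = build(beam_geometry, raw$beam_geometry),
       monitor_config = build(monitor_config, raw$monitor_config),
       feature_config = build(feature_config, raw$feature_config),
       seed = raw$seed %||% 1L)
}

#' @rdname read_config
#' @param config Named list of parameter objects (as from [read_config()]).
#' @export
write_config <- function(config, path) {
  strip <- function(x) { attributes(x)$class <- NULL; x }
  out <- lapply(config, function(x) if (is.list(x)) strip(x) else x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
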