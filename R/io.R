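# Plain-text / standard-format I/O. Images go through the tiff and png
# packages (Suggests); tables are CSV read into tibbles.

#' Read a calibrated image from TIFF or PNG
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param microns_per_pixel Calibration, µm per pixel.
#' @return A [calibrated_raster()].
#' @export
read_calibrated_image <- function(path, microns_per_pixel) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' is required to read TIFF", call. = FALSE)
      tiff::readTIFF(path)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("package 'png' is required to read PNG", call. = FALSE)
      png::readPNG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  calibrated_raster(px, microns_per_pixel)
}

#' Write an image array to TIFF or PNG
#'
#' @param image Matrix or RGB array in \[0, 1\] (e.g. `$image` from
#'   [generate_adipose_image()]), or a [calibrated_raster()].
#' @param path Destination path; format chosen by extension.
#' @export
write_image <- function(image, path) {
  if (inherits(image, "calibrated_raster")) image <- image$pixels
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' is required to write TIFF", call. = FALSE)
      tiff::writeTIFF(image, path)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("package 'png' is required to write PNG", call. = FALSE)
      png::writePNG(image, path)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Expects at least `set_id`, `is_case` and `age_years` columns; covariates
#' ride along as-is.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_cohort_csv <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  need <- c("set_id", "is_case", "age_years")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d$is_case <- as.logical(d$is_case)
  d
}

#' Read an age-specific rate table from CSV
#'
#' Columns `age`, `incidence_rate`, `mortality_rate` (per person-year).
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_rate_table_csv <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  need <- c("age", "incidence_rate", "mortality_rate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("rate table CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(d$incidence_rate < 0) || any(d$mortality_rate < 0))
    stop("rates must be >= 0", call. = FALSE)
  d
}

#' Write a tibble to CSV
#'
#' List-columns (contours, chord vectors) are dropped with a message, so
#' per-object and per-patient tables round-trip as plain text.
#'
#' @param x Tibble.
#' @param path Destination CSV path.
#' @export
write_table_csv <- function(x, path) {
  is_list <- vapply(x, is.list, logical(1))
  if (any(is_list)) {
    message("dropping list-column(s) for CSV: ",
            paste(names(x)[is_list], collapse = ", "))
    x <- x[, !is_list, drop = FALSE]
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
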