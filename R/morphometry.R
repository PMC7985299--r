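#' Calibrated raster
#'
#' Pairs an image array with its physical calibration. `pixels` is either an
#' `height x width` grayscale matrix or an `height x width x 3` RGB array with
#' values in \[0, 1\].
#'
#' @param pixels Image matrix or RGB array.
#' @param microns_per_pixel Calibration, µm per pixel (> 0).
#' @export
calibrated_raster <- function(pixels, microns_per_pixel) {
  stopifnot(microns_per_pixel > 0)
  d <- dim(pixels)
  if (is.null(d) || length(d) < 2 || d[1] < 1 || d[2] < 1)
    stop("pixels must be a non-empty matrix or H x W x 3 array", call. = FALSE)
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel),
            class = "calibrated_raster")
}

#' Segmentation and QC parameters
#'
#' @param luminance_threshold `"otsu"` (default) or a fixed value in \[0, 1\].
#'   Vacuole interiors are brighter than the stained background, so pixels
#'   above the threshold are candidate vacuole pixels.
#' @param min_diameter_um Minimum median chord diameter retained by
#'   [qc_filter()]; the 30 µm default separates mature adipocytes from
#'   artifacts and debris.
#' @param min_circularity Minimum `4*pi*A/P^2` retained (default 0.6).
#' @param min_regularity Minimum `min(chords)/max(chords)` retained
#'   (default 0.4).
#' @param exclude_border Drop objects touching the image border
#'   (default `TRUE`).
#' @param split_touching Apply a distance-transform watershed to split merged
#'   vacuoles (default `FALSE`).
#' @param duct_exclusion_um Objects any of whose pixels lie within this
#'   distance of a supplied duct mask are dropped (default 500 µm).
#' @export
segmentation_params <- function(luminance_threshold = "otsu",
                                min_diameter_um = 30,
                                min_circularity = 0.6,
                                min_regularity = 0.4,
                                exclude_border = TRUE,
                                split_touching = FALSE,
                                duct_exclusion_um = 500) {
  if (!identical(luminance_threshold, "otsu")) {
    stopifnot(is.numeric(luminance_threshold),
              luminance_threshold >= 0, luminance_threshold <= 1)
  }
  stopifnot(min_diameter_um >= 0, min_circularity >= 0, min_circularity <= 1,
            min_regularity >= 0, min_regularity <= 1, duct_exclusion_um >= 0)
  structure(list(luminance_threshold = luminance_threshold,
                 min_diameter_um = min_diameter_um,
                 min_circularity = min_circularity,
                 min_regularity = min_regularity,
                 exclude_border = exclude_border,
                 split_touching = split_touching,
                 duct_exclusion_um = duct_exclusion_um),
            class = "segmentation_params")
}

raster_luminance <- function(pixels) {
  if (length(dim(pixels)) == 3)
    0.2126 * pixels[, , 1] + 0.7152 * pixels[, , 2] + 0.0722 * pixels[, , 3]
  else pixels
}

#' Segment vacuole candidates from a calibrated raster
#'
#' Thresholds luminance (Otsu or fixed), fills holes, labels connected bright
#' regions, optionally splits touching cells with a distance-transform
#' watershed, removes border-touching objects and objects within
#' `duct_exclusion_um` of a duct mask, then extracts a sub-pixel iso-contour
#' and centroid per object.
#'
#' @param raster A [calibrated_raster()].
#' @param params A [segmentation_params()].
#' @param roi_mask,duct_mask Optional logical matrices on the raster grid:
#'   analysis region and DCIS-duct footprint.
#' @return Tibble with one row per object: `object_id`, `centroid_x_um`,
#'   `centroid_y_um`, `contour` (list-column of µm vertex matrices),
#'   `n_pixels`.
#' @export
segment_vacuoles <- function(raster, params = segmentation_params(),
                             roi_mask = NULL, duct_mask = NULL) {
  stopifnot(inherits(raster, "calibrated_raster"))
  mpp <- raster$microns_per_pixel
  lum <- raster_luminance(raster$pixels)
  nr <- nrow(lum); nc <- ncol(lum)
  for (m in list(roi_mask, duct_mask)) {
    if (!is.null(m) && !identical(dim(m), dim(lum)))
      stop("mask dimensions do not match the raster", call. = FALSE)
  }
  thr <- if (identical(params$luminance_threshold, "otsu")) {
    if (max(lum) - min(lum) < 1e-6) {
      warning("uniform image: no objects segmented")
      return(empty_segmentation())
    }
    EBImage::otsu(EBImage::Image(lum), range = c(0, 1))
  } else params$luminance_threshold
  bw <- lum > thr
  if (!is.null(roi_mask)) bw <- bw & roi_mask
  if (!any(bw)) return(empty_segmentation())
  bw <- EBImage::fillHull(EBImage::Image(bw * 1))
  lab <- if (isTRUE(params$split_touching)) {
    EBImage::watershed(EBImage::distmap(bw), tolerance = 3)
  } else EBImage::bwlabel(bw)
  lab <- EBImage::imageData(lab)
  if (params$exclude_border) {
    edge <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    lab[lab %in% setdiff(edge, 0)] <- 0
  }
  if (!is.null(duct_mask) && any(duct_mask)) {
    # distance (px) from every pixel to the duct footprint
    dist_px <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - duct_mask * 1)))
    zone <- dist_px <= params$duct_exclusion_um / mpp
    drop <- setdiff(unique(lab[zone]), 0)
    lab[lab %in% drop] <- 0
  }
  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  if (!length(ids)) return(empty_segmentation())
  rows <- purrr::map(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    m <- (lab[r0:r1, c0:c1, drop = FALSE] == id) * 1
    xy <- mask_contour(m, mpp)
    if (is.null(xy)) return(NULL)
    xy[, 1] <- xy[, 1] + (c0 - 1) * mpp
    xy[, 2] <- xy[, 2] + (r0 - 1) * mpp
    cen <- poly_centroid(xy)
    tibble::tibble(centroid_x_um = cen[1], centroid_y_um = cen[2],
                   contour = list(xy), n_pixels = nrow(idx))
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (!nrow(out)) return(empty_segmentation())
  dplyr::mutate(out, object_id = dplyr::row_number(), .before = 1)
}

empty_segmentation <- function() {
  tibble::tibble(object_id = integer(0), centroid_x_um = numeric(0),
                 centroid_y_um = numeric(0), contour = list(), n_pixels = integer(0))
}

#' Measure segmented objects with the 18-chord centroid rule
#'
#' For each object the centroid of its sub-pixel contour is computed and 18
#' chords are passed through it at 10-degree increments (0°..170°). The
#' median diameter is the median of the 18 chord lengths (mean of the 9th and
#' 10th order statistics). Area and perimeter come from the contour polygon;
#' circularity is `4*pi*A/P^2` and regularity `min(chords)/max(chords)`.
#' Objects whose centroid falls outside the contour (strongly non-convex)
#' are flagged unmeasurable.
#'
#' @param objects Output of [segment_vacuoles()] (or any tibble with a
#'   `contour` list-column of µm vertex matrices).
#' @return The input tibble with `area_um2`, `perimeter_um`, `chords_um`
#'   (list-column, 18 lengths), `median_diameter_um`, `circularity`,
#'   `regularity`, `measurable` appended.
#' @export
measure_objects <- function(objects) {
  stopifnot("contour" %in% names(objects))
  if (!nrow(objects)) {
    return(dplyr::mutate(objects, area_um2 = numeric(0), perimeter_um = numeric(0),
                         chords_um = list(), median_diameter_um = numeric(0),
                         circularity = numeric(0), regularity = numeric(0),
                         measurable = logical(0)))
  }
  meas <- purrr::map(objects$contour, function(xy) {
    a <- poly_area(xy)
    p <- poly_perimeter(xy)
    cen <- poly_centroid(xy)
    ok <- isTRUE(point_in_polygon(cen[1], cen[2], xy))
    ch <- if (ok) chord_lengths(xy, cen, chord_angles_18()) else rep(NA_real_, 18)
    list(area = a, perim = p, chords = ch,
         med = if (ok) median_chord(ch) else NA_real_,
         circ = 4 * pi * a / p^2,
         reg = if (ok && max(ch) > 0) min(ch) / max(ch) else NA_real_,
         ok = ok)
  })
  dplyr::mutate(objects,
    area_um2 = purrr::map_dbl(meas, "area"),
    perimeter_um = purrr::map_dbl(meas, "perim"),
    chords_um = purrr::map(meas, "chords"),
    median_diameter_um = purrr::map_dbl(meas, "med"),
    circularity = purrr::map_dbl(meas, "circ"),
    regularity = purrr::map_dbl(meas, "reg"),
    measurable = purrr::map_lgl(meas, "ok"))
}

#' QC-filter measured objects
#'
#' Applies the size / roundness / chord-regularity rules: objects are kept
#' when `median_diameter_um >= min_diameter_um`, `circularity >=
#' min_circularity` and `regularity >= min_regularity`. Every rejection
#' carries a machine-readable reason string (comma-joined when several rules
#' fail). Unmeasurable objects are always rejected.
#'
#' @param objects Output of [measure_objects()].
#' @param params A [segmentation_params()].
#' @return The input tibble with `qc_pass` and `qc_reason` appended.
#' @export
qc_filter <- function(objects, params = segmentation_params()) {
  if (!nrow(objects)) {
    return(dplyr::mutate(objects, qc_pass = logical(0), qc_reason = character(0)))
  }
  reasons <- purrr::pmap_chr(
    list(objects$median_diameter_um, objects$circularity, objects$regularity,
         objects$measurable),
    function(d, c, r, ok) {
      if (!isTRUE(ok)) return("unmeasurable")
      rr <- character(0)
      if (d < params$min_diameter_um) rr <- c(rr, "min_diameter")
      if (c < params$min_circularity) rr <- c(rr, "min_circularity")
      if (r < params$min_regularity) rr <- c(rr, "min_regularity")
      paste(rr, collapse = ",")
    })
  dplyr::mutate(objects, qc_pass = reasons == "", qc_reason = reasons)
}

#' Summarise a patient's adipocyte population at the 75th percentile
#'
#' The patient-level size score is the 75th percentile of the per-adipocyte
#' distribution, computed by linear interpolation between closest ranks
#' (`stats::quantile` type 7). A patient with zero QC-passing objects is not
#' assessable and yields no profile row (with a warning).
#'
#' @param objects Measured, QC-annotated objects; only rows with
#'   `qc_pass == TRUE` contribute. If a `patient_id` column is present the
#'   summary is per patient, else `patient_id` labels all rows.
#' @param patient_id Label used when `objects` has no `patient_id` column.
#' @return Tibble with `patient_id`, `n_objects_measured`, `diameter_p75_um`,
#'   `area_p75_um2`, `mean_area_um2`.
#' @export
summarize_patients <- function(objects, patient_id = "patient") {
  if (!"patient_id" %in% names(objects))
    objects <- dplyr::mutate(objects, patient_id = patient_id)
  if (!"qc_pass" %in% names(objects)) objects <- dplyr::mutate(objects, qc_pass = TRUE)
  all_ids <- unique(objects$patient_id)
  kept <- dplyr::filter(objects, .data$qc_pass)
  lost <- setdiff(all_ids, unique(kept$patient_id))
  if (length(lost))
    warning("not assessable (zero QC-passing adipocytes): ",
            paste(lost, collapse = ", "))
  kept |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_objects_measured = dplyr::n(),
      diameter_p75_um = stats::quantile(.data$median_diameter_um, 0.75,
                                        names = FALSE, type = 7),
      area_p75_um2 = stats::quantile(.data$area_um2, 0.75, names = FALSE, type = 7),
      mean_area_um2 = mean(.data$area_um2),
      .groups = "drop")
}

#' Full morphometry pipeline on one raster
#'
#' Convenience wrapper: [segment_vacuoles()] then [measure_objects()] then
#' [qc_filter()].
#'
#' @inheritParams segment_vacuoles
#' @return Measured, QC-annotated object tibble.
#' @export
measure_adipocytes <- function(raster, params = segmentation_params(),
                               roi_mask = NULL, duct_mask = NULL) {
  segment_vacuoles(raster, params, roi_mask, duct_mask) |>
    measure_objects() |>
    qc_filter(params)
}
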