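# Crown-like structure (CLS) detection: an adipocyte ringed by CD68-positive
# macrophages, counted per 10 cm^2 of adipose tissue.

# Ruifrok-Johnston H-DAB optical-density vectors (rows: haematoxylin, DAB,
# residual), each normalised to unit length.
hdab_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  rbind(h / sqrt(sum(h^2)), d / sqrt(sum(d^2)), r / sqrt(sum(r^2)))
}

#' CD68-positive mask by H-DAB colour deconvolution
#'
#' Converts an RGB IHC raster to optical density, unmixes it with the fixed
#' Ruifrok-Johnston haematoxylin/DAB vectors, and thresholds the DAB
#' concentration channel.
#'
#' @param raster A [calibrated_raster()] holding an RGB image, or an RGB
#'   array in \[0, 1\].
#' @param dab_threshold Threshold on the DAB optical-density channel
#'   (default 0.25); `0` marks every pixel with any absorbance.
#' @return Logical height x width matrix of CD68-positive pixels.
#' @export
cd68_positive_mask <- function(raster, dab_threshold = 0.25) {
  px <- if (inherits(raster, "calibrated_raster")) raster$pixels else raster
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("cd68_positive_mask needs an RGB raster (grayscale input is invalid)",
         call. = FALSE)
  d <- dim(px)
  rgb <- matrix(px, ncol = 3)
  od <- -log10(pmax(rgb, 1 / 255))
  conc <- od %*% solve(hdab_stain_matrix())
  dab <- pmax(conc[, 2], 0)            # negative concentrations are unphysical
  matrix(dab >= dab_threshold & rowSums(od) > 1e-3, d[1], d[2])
}

#' Score adipocytes for crown-like structures
#'
#' For each measured adipocyte, the peri-adipocyte annulus (pixels within
#' `annulus_width_um` outside the contour) is divided into `n_arc_bins`
#' angular bins about the centroid; a bin is positive when more than half of
#' its annulus pixels are CD68-positive. `annulus_coverage` is the fraction
#' of non-empty bins that are positive, and `is_cls` tests it against
#' `coverage_threshold`.
#'
#' @param objects Tibble with a `contour` list-column (µm), e.g. from
#'   [measure_adipocytes()].
#' @param cd68_mask Logical CD68-positive matrix on the image grid.
#' @param microns_per_pixel Calibration of `cd68_mask`.
#' @param annulus_width_um Rim search width (default 20 µm, the scale of a
#'   macrophage rim).
#' @param coverage_threshold Minimum arc coverage called a CLS
#'   (default 0.33).
#' @param n_arc_bins Angular resolution of the coverage estimate.
#' @return Tibble: `object_id`, `annulus_coverage`, `is_cls`. Objects whose
#'   annulus lies entirely off-canvas are skipped with a warning.
#' @export
detect_cls <- function(objects, cd68_mask, microns_per_pixel,
                       annulus_width_um = 20, coverage_threshold = 0.33,
                       n_arc_bins = 36) {
  stopifnot("contour" %in% names(objects), is.matrix(cd68_mask) || is.logical(cd68_mask))
  hpx <- nrow(cd68_mask); wpx <- ncol(cd68_mask)
  mpp <- microns_per_pixel
  ids <- objects$object_id %||% seq_len(nrow(objects))
  rows <- purrr::map(seq_len(nrow(objects)), function(i) {
    ann <- annulus_pixels(objects$contour[[i]], annulus_width_um, mpp, hpx, wpx)
    if (!nrow(ann$px)) {
      warning("object ", ids[i], ": annulus off-canvas, coverage undefined; skipped")
      return(NULL)
    }
    bin <- pmin(floor(ann$angle / (2 * pi) * n_arc_bins) + 1L, n_arc_bins)
    pos <- cd68_mask[ann$px]
    per_bin <- tapply(pos, factor(bin, levels = seq_len(n_arc_bins)), mean)
    nonempty <- !is.na(per_bin)
    cov <- mean(per_bin[nonempty] > 0.5)
    tibble::tibble(object_id = ids[i], annulus_coverage = cov,
                   is_cls = cov >= coverage_threshold)
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' CLS density per 10 cm^2 of adipose tissue
#'
#' @param n_cls CLS count, summed over a patient's sections.
#' @param adipose_area_cm2 Adipose area in cm^2, summed over the same
#'   sections (> 0).
#' @param high_threshold Density (per 10 cm^2) at and above which the
#'   category is `"high"` (default 5).
#' @return Tibble: `n_cls`, `adipose_area_cm2`, `cls_per_10cm2`, `category`
#'   (`"high"` when `cls_per_10cm2 >= high_threshold`, else `"low"`).
#' @export
cls_density <- function(n_cls, adipose_area_cm2, high_threshold = 5) {
  if (any(adipose_area_cm2 <= 0))
    stop("adipose_area_cm2 must be > 0 (density undefined)", call. = FALSE)
  stopifnot(all(n_cls >= 0))
  dens <- 10 * n_cls / adipose_area_cm2
  tibble::tibble(n_cls = n_cls, adipose_area_cm2 = adipose_area_cm2,
                 cls_per_10cm2 = dens,
                 category = ifelse(dens >= high_threshold, "high", "low"))
}
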