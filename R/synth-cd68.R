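#' Add a synthetic CD68 macrophage-rim overlay
#'
#' Flags a fraction of the generated adipocytes as crown-like structures
#' (CLS) and paints an annular CD68-positive rim around each: pixels outside
#' the cell polygon, within `rim_width_um` of it, and inside an arc spanning
#' `rim_coverage` of the full circle (random phase per object).
#'
#' @param adipo An object returned by [generate_adipose_image()].
#' @param cls_fraction Fraction of intact (non-artifact, non-debris) cells to
#'   flag as CLS, in \[0, 1\].
#' @param rim_coverage Fraction of each flagged cell's boundary arc covered
#'   by the rim, in \[0, 1\].
#' @param rim_width_um Radial thickness of the rim, µm.
#' @param seed Integer seed.
#' @return A list with `mask` (logical height x width matrix of CD68-positive
#'   pixels) and `objects` (the ground-truth tibble with `is_cls` updated).
#' @export
generate_cd68_overlay <- function(adipo, cls_fraction, rim_coverage,
                                  rim_width_um = 20, seed = 1L) {
  if (!is.numeric(cls_fraction) || cls_fraction < 0 || cls_fraction > 1)
    stop("cls_fraction must be in [0, 1]", call. = FALSE)
  if (!is.numeric(rim_coverage) || rim_coverage < 0 || rim_coverage > 1)
    stop("rim_coverage must be in [0, 1]", call. = FALSE)
  mpp <- adipo$microns_per_pixel
  hpx <- dim(adipo$image)[1]; wpx <- dim(adipo$image)[2]
  objects <- adipo$objects
  mask <- matrix(FALSE, hpx, wpx)
  eligible <- which(!objects$is_artifact & !objects$is_debris)
  n_cls <- round(cls_fraction * length(eligible))
  objects$is_cls <- FALSE
  if (n_cls > 0 && rim_coverage > 0) {
    withr::with_seed(seed, {
      chosen <- sample(eligible, n_cls)
      for (i in chosen) {
        ann <- annulus_pixels(objects$polygon[[i]], rim_width_um, mpp, hpx, wpx)
        if (!nrow(ann$px)) next
        phase <- stats::runif(1, 0, 2 * pi)
        rel <- (ann$angle - phase) %% (2 * pi)
        sel <- rel <= rim_coverage * 2 * pi
        mask[ann$px[sel, , drop = FALSE]] <- TRUE
      }
      objects$is_cls[chosen] <- TRUE
    })
  } else if (n_cls > 0) {
    withr::with_seed(seed, objects$is_cls[sample(eligible, n_cls)] <- TRUE)
  }
  list(mask = mask, objects = objects)
}

# Pixels outside `poly` within `width_um` of it, on the full-image grid, with
# their polar angle about the polygon centroid. Distance via EBImage distmap
# on a padded crop.
annulus_pixels <- function(poly, width_um, mpp, hpx, wpx) {
  wpxl <- ceiling(width_um / mpp) + 2L
  r0 <- max(1L, floor(min(poly[, 2]) / mpp) - wpxl)
  r1 <- min(hpx, ceiling(max(poly[, 2]) / mpp) + wpxl)
  c0 <- max(1L, floor(min(poly[, 1]) / mpp) - wpxl)
  c1 <- min(wpx, ceiling(max(poly[, 1]) / mpp) + wpxl)
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  g <- expand.grid(r = seq.int(r0, r1), c = seq.int(c0, c1))
  obj <- matrix(point_in_polygon((g$c - 0.5) * mpp, (g$r - 0.5) * mpp, poly), nr, nc)
  dist_px <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - obj * 1)))
  ann <- !obj & dist_px <= width_um / mpp & dist_px > 0
  idx <- which(ann, arr.ind = TRUE)
  if (!nrow(idx)) return(list(px = cbind(integer(0), integer(0)), angle = numeric(0)))
  rr <- idx[, 1] + r0 - 1L; cc <- idx[, 2] + c0 - 1L
  cen <- poly_centroid(poly)
  ang <- atan2((rr - 0.5) * mpp - cen[2], (cc - 0.5) * mpp - cen[1]) %% (2 * pi)
  list(px = cbind(rr, cc), angle = ang)
}

#' Render a CD68 IHC-style RGB raster from an overlay mask
#'
#' Paints a haematoxylin-counterstained scene (bluish tissue, bright vacuole
#' interiors) with DAB-brown pixels wherever the CD68 mask is positive, so
#' that stain separation in [cd68_positive_mask()] can be exercised end to
#' end.
#'
#' @param adipo An object from [generate_adipose_image()].
#' @param mask Logical CD68-positive mask on the same grid.
#' @return A height x width x 3 array in \[0, 1\].
#' @export
render_cd68_ihc <- function(adipo, mask) {
  img <- adipo$image
  hpx <- dim(img)[1]; wpx <- dim(img)[2]
  stopifnot(identical(dim(mask), c(hpx, wpx)))
  lum <- raster_luminance(img)
  out <- array(0, dim = c(hpx, wpx, 3))
  bright <- lum > 0.9
  # haematoxylin counterstain: blue-grey tissue, near-white vacuoles
  out[, , 1] <- ifelse(bright, 0.94, 0.62)
  out[, , 2] <- ifelse(bright, 0.94, 0.66)
  out[, , 3] <- ifelse(bright, 0.96, 0.84)
  dab <- c(0.45, 0.28, 0.13)
  for (k in 1:3) {
    ch <- out[, , k]
    ch[mask] <- dab[k]
    out[, , k] <- ch
  }
  out
}
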