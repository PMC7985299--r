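#' Specify a synthetic adipose-tissue image
#'
#' Builds the parameter object consumed by [generate_adipose_image()]. The
#' generator emulates an H&E field of packed, intact adipocytes: bright lipid
#' vacuoles separated by stained membranes, optionally with torn-cell
#' artifacts, sub-30-µm debris and a stromal band.
#'
#' @param width_px,height_px Canvas size in pixels.
#' @param microns_per_pixel Calibration, µm per pixel (> 0).
#' @param n_cells Number of intact adipocytes to place.
#' @param diameter_dist Target cell-diameter distribution: a list with
#'   `family` `"lognormal"` (fields `meanlog`, `sdlog`, log-µm scale) or
#'   `"constant"` (field `value_um`).
#' @param membrane_thickness_um Stained gap between neighbouring cells, µm.
#' @param artifact_fraction Torn crescent-shaped objects added on top of
#'   `n_cells`, as a fraction of `n_cells` (in \[0, 1\]).
#' @param small_debris_count Number of debris objects with diameter < 30 µm.
#' @param stroma_fraction Fraction of canvas width reserved for a stromal
#'   band in which no adipocytes are placed (in \[0, 1\]).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return An object of class `adipo_image_spec`.
#' @export
adipo_image_spec <- function(width_px = 2048, height_px = 2048,
                             microns_per_pixel = 0.5, n_cells = 100,
                             diameter_dist = list(family = "lognormal",
                                                  meanlog = log(65), sdlog = 0.3),
                             membrane_thickness_um = 4,
                             artifact_fraction = 0,
                             small_debris_count = 0,
                             stroma_fraction = 0,
                             seed = 1L) {
  stopifnot(width_px >= 8, height_px >= 8, microns_per_pixel > 0,
            n_cells >= 0, membrane_thickness_um >= 0,
            artifact_fraction >= 0, artifact_fraction <= 1,
            stroma_fraction >= 0, stroma_fraction <= 1,
            small_debris_count >= 0)
  fam <- diameter_dist$family %||% "lognormal"
  if (!fam %in% c("lognormal", "constant"))
    stop("diameter_dist$family must be 'lognormal' or 'constant'", call. = FALSE)
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 microns_per_pixel = microns_per_pixel, n_cells = as.integer(n_cells),
                 diameter_dist = diameter_dist,
                 membrane_thickness_um = membrane_thickness_um,
                 artifact_fraction = artifact_fraction,
                 small_debris_count = as.integer(small_debris_count),
                 stroma_fraction = stroma_fraction, seed = as.integer(seed)),
            class = "adipo_image_spec")
}

draw_diameters <- function(dist, n) {
  if (n == 0) return(numeric(0))
  switch(dist$family,
         constant = rep(dist$value_um, n),
         lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog))
}

# Crescent (annulus-sector) polygon: fails roundness and chord-regularity QC
# by construction. The default span/thickness keep the centroid inside the
# material so the object is measurable (and then rejected on its merits).
crescent_polygon <- function(center, r_outer, span_deg = 120, r_ratio = 0.55,
                             phase = 0) {
  th <- phase + seq(0, span_deg, length.out = 60) * pi / 180
  outer <- cbind(center[1] + r_outer * cos(th), center[2] + r_outer * sin(th))
  inner <- cbind(center[1] + r_ratio * r_outer * cos(rev(th)),
                 center[2] + r_ratio * r_outer * sin(rev(th)))
  rbind(outer, inner)
}

# Sequential dart-throwing with per-object radii; errors out when the canvas
# cannot host the requested count (never silently truncates).
place_centers <- function(radii, xlim, ylim, membrane, max_tries = 40000) {
  n <- length(radii)
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    lo_x <- xlim[1] + radii[i]; hi_x <- xlim[2] - radii[i]
    lo_y <- ylim[1] + radii[i]; hi_y <- ylim[2] - radii[i]
    if (lo_x >= hi_x || lo_y >= hi_y)
      stop("packing failure: object ", i, " does not fit the placement region",
           call. = FALSE)
    for (tr in seq_len(max_tries)) {
      x <- stats::runif(1, lo_x, hi_x); y <- stats::runif(1, lo_y, hi_y)
      if (i == 1L ||
          all((cx[seq_len(i - 1)] - x)^2 + (cy[seq_len(i - 1)] - y)^2 >=
              (radii[seq_len(i - 1)] + radii[i] + membrane)^2)) {
        cx[i] <- x; cy[i] <- y; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("packing failure: could not place object ", i, " of ", n,
           " (canvas too small for requested cells)", call. = FALSE)
  }
  cbind(cx, cy)
}

# Additively weighted bisector clipping: convex cell polygons with an exact
# membrane gap, capped by a 72-gon of the target radius.
voronoi_cell <- function(i, centers, radii, membrane, xlim, ylim) {
  p <- centers[i, ]; r <- radii[i]
  poly <- regular_ngon(p, r, n = 72)
  # canvas inset
  half <- membrane / 2
  poly <- clip_halfplane(poly, c(-1, 0), -(xlim[1] + half))
  poly <- clip_halfplane(poly, c(1, 0), xlim[2] - half)
  poly <- clip_halfplane(poly, c(0, -1), -(ylim[1] + half))
  poly <- clip_halfplane(poly, c(0, 1), ylim[2] - half)
  d2 <- (centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2
  near <- which(d2 < (r + radii + membrane + 1e-9)^2 & seq_along(d2) != i)
  for (j in near) {
    if (is.null(poly)) break
    q <- centers[j, ]
    dd <- sqrt(d2[j])
    nrm <- (q - p) / dd
    cut <- (dd + radii[i] - radii[j]) / 2 - half   # distance from p along nrm
    poly <- clip_halfplane(poly, nrm, sum(nrm * p) + cut)
  }
  poly
}

#' Generate a ground-truthed synthetic adipose image
#'
#' Places `n_cells` adipocytes by Poisson-disk (dart-throwing) sampling,
#' carves each cell as a convex polygon (additively weighted bisectors with an
#' exact membrane offset, capped by the target diameter), then renders bright
#' vacuole interiors on a stained background. Optional crescent artifacts,
#' sub-30-µm debris and a stromal band exercise downstream QC.
#'
#' @param spec An [adipo_image_spec()].
#' @return A list with `image` (height x width x 3 array in \[0, 1\]),
#'   `microns_per_pixel`, and `objects`: a tibble with one row per placed
#'   object (`object_id`, `centroid_x_um`, `centroid_y_um`, `polygon`
#'   list-column of µm vertex matrices, `true_area_um2`,
#'   `true_median_diameter_um` from the 18-chord rule applied to the exact
#'   polygon, `is_artifact`, `is_debris`, `is_cls`).
#' @export
generate_adipose_image <- function(spec) {
  stopifnot(inherits(spec, "adipo_image_spec"))
  mpp <- spec$microns_per_pixel
  W <- spec$width_px * mpp; H <- spec$height_px * mpp
  withr::with_seed(spec$seed, {
    stroma_x <- W * (1 - spec$stroma_fraction)  # stroma band on the right
    n_art <- round(spec$artifact_fraction * spec$n_cells)
    diam <- draw_diameters(spec$diameter_dist, spec$n_cells)
    art_r <- if (n_art > 0) stats::runif(n_art, 20, 35) else numeric(0)
    deb_d <- if (spec$small_debris_count > 0)
      stats::runif(spec$small_debris_count, 8, 25) else numeric(0)
    radii <- c(diam / 2, art_r, deb_d / 2)
    kind <- rep(c("cell", "artifact", "debris"),
                c(spec$n_cells, n_art, spec$small_debris_count))
    # large objects first: sequential disk packing jams far later this way
    ord <- order(radii, decreasing = TRUE)
    radii <- radii[ord]; kind <- kind[ord]
    margin <- spec$membrane_thickness_um
    centers <- place_centers(radii, c(margin, stroma_x - margin),
                             c(margin, H - margin), spec$membrane_thickness_um)
    n_tot <- length(radii)
    polys <- vector("list", n_tot)
    for (i in seq_len(n_tot)) {
      polys[[i]] <- switch(kind[i],
        cell = voronoi_cell(i, centers, radii, spec$membrane_thickness_um,
                            c(0, W), c(0, H)),
        artifact = crescent_polygon(centers[i, ], radii[i],
                                    phase = stats::runif(1, 0, 2 * pi)),
        debris = regular_ngon(centers[i, ], radii[i], n = 36))
      if (is.null(polys[[i]]))
        stop("packing failure: cell ", i, " was clipped away entirely",
             call. = FALSE)
    }
    img <- render_adipose(polys, spec, stroma_x)
    objects <- tibble::tibble(
      object_id = seq_len(n_tot),
      centroid_x_um = vapply(polys, function(p) poly_centroid(p)[1], numeric(1)),
      centroid_y_um = vapply(polys, function(p) poly_centroid(p)[2], numeric(1)),
      polygon = polys,
      true_area_um2 = vapply(polys, poly_area, numeric(1)),
      true_median_diameter_um = vapply(polys, function(p) {
        median_chord(chord_lengths(p, poly_centroid(p), chord_angles_18()))
      }, numeric(1)),
      is_artifact = kind == "artifact",
      is_debris = kind == "debris",
      is_cls = FALSE)
  })
  list(image = img, microns_per_pixel = mpp, objects = objects)
}

render_adipose <- function(polys, spec, stroma_x) {
  hpx <- spec$height_px; wpx <- spec$width_px; mpp <- spec$microns_per_pixel
  npx <- hpx * wpx
  # stained background (eosin/haematoxylin mix) with mild texture
  base <- c(0.78, 0.52, 0.64)
  noise <- matrix(stats::runif(npx, -0.03, 0.03), hpx, wpx)
  R <- base[1] + noise; G <- base[2] + noise; B <- base[3] + noise
  scol <- ceiling(stroma_x / mpp)
  if (scol < wpx) {
    cols <- seq.int(max(1L, scol), wpx)
    fib <- outer(sin(seq_len(hpx) / 6), rep(1, length(cols))) * 0.05
    R[, cols] <- 0.88 + fib + noise[, cols]
    G[, cols] <- 0.62 + fib + noise[, cols]
    B[, cols] <- 0.72 + fib + noise[, cols]
  }
  for (p in polys) {
    idx <- rasterize_polygon(p, wpx, hpx, mpp)
    if (!length(idx)) next
    lum <- 0.955 + stats::runif(length(idx), -0.015, 0.015)
    R[idx] <- lum; G[idx] <- lum; B[idx] <- lum + 0.01
  }
  arr <- array(0, dim = c(hpx, wpx, 3))
  arr[, , 1] <- pmin(pmax(R, 0), 1)
  arr[, , 2] <- pmin(pmax(G, 0), 1)
  arr[, , 3] <- pmin(pmax(B, 0), 1)
  arr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
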