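# Shared fixtures, built in code at test time.

ngon <- function(center, r, n = 720, phase = 0) {
  th <- phase + seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_poly <- function(center, a, b, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + a * cos(th), center[2] + b * sin(th))
}

square_poly <- function(center, side) {
  h <- side / 2
  cbind(center[1] + c(-h, h, h, -h), center[2] + c(-h, -h, h, h))
}

# Render a single bright shape on a stained background as a calibrated
# raster; the segmentation path then sees the same kind of input as real
# slides.
shape_raster <- function(poly, mpp, pad_um = 20) {
  w_um <- max(poly[, 1]) + pad_um
  h_um <- max(poly[, 2]) + pad_um
  stopifnot(min(poly) > pad_um / 2)
  wpx <- ceiling(w_um / mpp); hpx <- ceiling(h_um / mpp)
  g <- expand.grid(i = seq_len(wpx), j = seq_len(hpx))
  inside <- adiposize:::point_in_polygon((g$i - 0.5) * mpp, (g$j - 0.5) * mpp, poly)
  m <- matrix(0.30, hpx, wpx)
  m[(g$i[inside] - 1L) * hpx + g$j[inside]] <- 0.95
  arr <- array(rep(m, 3), dim = c(hpx, wpx, 3))
  calibrated_raster(arr, mpp)
}

# Brute-force chord oracle: walk the line through `center` at angle `theta`
# in fine steps and sum the in-polygon step lengths. Independent of the
# edge-intersection algorithm used by the package.
brute_chord <- function(poly, center, theta, step = 0.05, reach = 400) {
  tt <- seq(-reach, reach, by = step)
  px <- center[1] + tt * cos(theta)
  py <- center[2] + tt * sin(theta)
  sum(adiposize:::point_in_polygon(px, py, poly)) * step
}

# Tiny matched-pair cohort with given discordant counts (case-exposed /
# control-exposed pairs) plus concordant padding.
paired_cohort <- function(n10, n01, n_conc = 5) {
  dplyr::bind_rows(
    purrr::map(seq_len(n10), ~ tibble::tibble(set_id = .x, is_case = c(TRUE, FALSE), x = c(1, 0))),
    purrr::map(seq_len(n01), ~ tibble::tibble(set_id = n10 + .x, is_case = c(TRUE, FALSE), x = c(0, 1))),
    purrr::map(seq_len(n_conc), ~ tibble::tibble(set_id = n10 + n01 + .x, is_case = c(TRUE, FALSE), x = c(1, 1))))
}

texture_patch_set <- function(n_per_class = 40, size_px = 64, seed0 = 100) {
  cls <- c("adipose", "stroma", "epithelium")
  tibble::tibble(
    label = rep(cls, each = n_per_class),
    pixels = purrr::flatten(purrr::map(cls, function(cl) {
      purrr::map(seq_len(n_per_class),
                 ~ make_texture_patch(cl, size_px, seed = seed0 + .x +
                                        match(cl, cls) * 1000))
    })))
}
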