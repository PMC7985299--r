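# Planar geometry primitives shared by the synthetic generator and the
# morphometry pipeline. Polygons are n x 2 matrices of (x, y) vertices in µm,
# implicitly closed, x right / y down. Pixel (col i, row j) has its centre at
# ((i - 0.5) * mpp, (j - 0.5) * mpp).

poly_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

poly_perimeter <- function(xy) {
  dx <- diff(c(xy[, 1], xy[1, 1]))
  dy <- diff(c(xy[, 2], xy[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}

# Area-weighted centroid (exact for simple polygons, sign-safe).
poly_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Even-odd point-in-polygon test, vectorised over query points.
point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Total in-polygon length of the line through `center` at each angle (radians).
# For convex shapes this is the extreme-to-extreme chord; for mildly irregular
# contours the even-odd intervals along the line are summed.
chord_lengths <- function(xy, center, angles) {
  ax <- xy[, 1] - center[1]
  ay <- xy[, 2] - center[2]
  bx <- c(ax[-1], ax[1])
  by <- c(ay[-1], ay[1])
  vapply(angles, function(theta) {
    ux <- cos(theta); uy <- sin(theta)
    sa <- ux * ay - uy * ax          # signed perp offset of vertex a
    sb <- ux * by - uy * bx
    sa[sa == 0] <- .Machine$double.eps   # nudge on-line vertices off the line
    sb[sb == 0] <- .Machine$double.eps
    hit <- (sa > 0) != (sb > 0)
    if (!any(hit)) return(0)
    lam <- sa[hit] / (sa[hit] - sb[hit])
    ix <- ax[hit] + lam * (bx[hit] - ax[hit])
    iy <- ay[hit] + lam * (by[hit] - ay[hit])
    tt <- sort(ix * ux + iy * uy)
    if (length(tt) %% 2 == 1) tt <- tt[-length(tt)]  # degenerate grazing hit
    if (!length(tt)) return(0)
    sum(tt[seq(2, length(tt), by = 2)] - tt[seq(1, length(tt), by = 2)])
  }, numeric(1))
}

# The 18 study angles: 10-degree increments, 0..170 degrees.
chord_angles_18 <- function() seq(0, 170, by = 10) * pi / 180

# Median of the 18 chords: mean of the 9th and 10th order statistics.
median_chord <- function(chords) {
  s <- sort(chords)
  k <- length(s) %/% 2
  if (length(s) %% 2 == 0) (s[k] + s[k + 1]) / 2 else s[k + 1]
}

regular_ngon <- function(center, r, n = 72, phase = 0) {
  th <- phase + seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# Sutherland-Hodgman clip of a convex polygon against half-plane {x : n.x <= d}.
clip_halfplane <- function(xy, nrm, d) {
  if (is.null(xy) || nrow(xy) < 3) return(NULL)
  s <- xy %*% nrm - d
  n <- nrow(xy)
  out <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ins_i <- s[i] <= 0; ins_j <- s[j] <= 0
    if (ins_i) { k <- k + 1L; out[[k]] <- xy[i, ] }
    if (ins_i != ins_j) {
      lam <- s[i] / (s[i] - s[j])
      k <- k + 1L
      out[[k]] <- xy[i, ] + lam * (xy[j, ] - xy[i, ])
    }
  }
  if (k < 3L) return(NULL)
  do.call(rbind, out[seq_len(k)])
}

# Indices (linear, column-major over a height x width grid) of pixels whose
# centres fall inside the polygon (coordinates in µm, calibration mpp µm/px).
rasterize_polygon <- function(xy, width_px, height_px, mpp) {
  i0 <- max(1L, floor(min(xy[, 1]) / mpp - 1))
  i1 <- min(width_px, ceiling(max(xy[, 1]) / mpp + 1))
  j0 <- max(1L, floor(min(xy[, 2]) / mpp - 1))
  j1 <- min(height_px, ceiling(max(xy[, 2]) / mpp + 1))
  if (i0 > i1 || j0 > j1) return(integer(0))
  ii <- seq.int(i0, i1); jj <- seq.int(j0, j1)
  g <- expand.grid(i = ii, j = jj)
  keep <- point_in_polygon((g$i - 0.5) * mpp, (g$j - 0.5) * mpp, xy)
  (g$i[keep] - 1L) * height_px + g$j[keep]
}

# Sub-pixel iso-contour (level 0.5) of a binary mask, via marching squares
# (grDevices::contourLines). Returns the longest closed contour as an n x 2
# matrix in µm, or NULL when no contour exists.
mask_contour <- function(mask, mpp) {
  nr <- nrow(mask); nc <- ncol(mask)
  # pad so border-touching objects still close
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- mask
  # contourLines treats z as z[x, y]; our rows are y (image rows), so transpose
  xs <- ((seq_len(nc + 2)) - 1.5) * mpp   # pixel-centre coords incl. pad
  ys <- ((seq_len(nr + 2)) - 1.5) * mpp
  cl <- grDevices::contourLines(x = xs, y = ys, z = t(z), levels = 0.5)
  if (!length(cl)) return(NULL)
  lens <- vapply(cl, function(cc) length(cc$x), integer(1))
  best <- cl[[which.max(lens)]]
  xy <- cbind(best$x, best$y)
  if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) < 3) return(NULL)
  xy
}
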