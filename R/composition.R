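# Tissue compartment classification: adipose / stroma / epithelium area
# fractions per slide, via hand-crafted colour-texture features and a
# random-forest tile classifier.

#' Colour-texture features of an image tile
#'
#' Per-channel intensity mean and standard deviation, luminance mean and
#' standard deviation, bright and dark pixel fractions, and a local gradient
#' energy. Deterministic summaries adequate for compartment-level area
#' fractions.
#'
#' @param tile Grayscale matrix or RGB array in \[0, 1\].
#' @return Named numeric vector of 9 features.
#' @export
tile_features <- function(tile) {
  if (length(dim(tile)) == 3) {
    ch <- list(r = tile[, , 1], g = tile[, , 2], b = tile[, , 3])
  } else {
    ch <- list(r = tile, g = tile, b = tile)
  }
  lum <- 0.2126 * ch$r + 0.7152 * ch$g + 0.0722 * ch$b
  grad <- mean(abs(diff(lum))) + mean(abs(t(diff(t(lum)))))
  c(mean_r = mean(ch$r), mean_g = mean(ch$g), mean_b = mean(ch$b),
    sd_r = stats::sd(ch$r), sd_g = stats::sd(ch$g),
    lum_mean = mean(lum), lum_sd = stats::sd(lum),
    frac_bright = mean(lum > 0.85), grad_energy = grad)
}

#' Synthetic texture patch for one tissue compartment
#'
#' Compartment look-alikes for training and testing the tile classifier:
#' adipose (bright vacuole interiors crossed by thin stained membranes),
#' stroma (pink fibrous waves), epithelium (densely haematoxylin-stained
#' speckle).
#'
#' @param class `"adipose"`, `"stroma"` or `"epithelium"`.
#' @param size_px Patch side length in pixels.
#' @param seed Integer seed.
#' @return `size_px x size_px x 3` array in \[0, 1\].
#' @export
make_texture_patch <- function(class = c("adipose", "stroma", "epithelium"),
                               size_px = 64, seed = 1L) {
  class <- match.arg(class)
  withr::with_seed(seed, {
    n <- size_px
    noise <- matrix(stats::runif(n * n, -0.03, 0.03), n, n)
    out <- array(0, dim = c(n, n, 3))
    if (class == "adipose") {
      base <- matrix(0.95, n, n) + noise
      # thin stained membrane lines
      k <- max(2L, round(n / 10))
      lines_at <- seq(sample.int(k, 1), n, by = k)
      base[lines_at, ] <- 0.62
      base[, lines_at] <- 0.62
      out[, , 1] <- base; out[, , 2] <- base - 0.08 * (base < 0.8)
      out[, , 3] <- base + 0.01
    } else if (class == "stroma") {
      ph <- stats::runif(1, 0, 2 * pi)
      fib <- outer(sin(seq_len(n) / 4 + ph), rep(1, n)) * 0.06
      out[, , 1] <- 0.87 + fib + noise
      out[, , 2] <- 0.60 + fib + noise
      out[, , 3] <- 0.70 + fib + noise
    } else {
      sp <- matrix(stats::rbinom(n * n, 1, 0.45), n, n) * 0.25
      out[, , 1] <- 0.45 - sp + noise
      out[, , 2] <- 0.30 - sp + noise
      out[, , 3] <- 0.55 - sp + noise
    }
    pmin(pmax(out, 0), 1)
  })
}

#' Train the compartment classifier
#'
#' Fits a random forest (bagged decision trees, deterministic per seed) on
#' labelled patches and reports holdout accuracy on a 20\% split.
#'
#' @param patches Tibble with a `label` column (character/factor) and a
#'   `pixels` list-column of image tiles (see [make_texture_patch()]).
#' @param seed Integer seed controlling both the split and the forest.
#' @param n_trees Number of trees (default 200).
#' @return Object of class `compartment_classifier` with the fitted forest,
#'   feature names, class levels and `holdout_accuracy`.
#' @export
train_compartment_classifier <- function(patches, seed = 1L, n_trees = 200) {
  if (!nrow(patches)) stop("empty patch list", call. = FALSE)
  y <- factor(patches$label)
  if (nlevels(y) < 2)
    stop("training set must contain >= 2 classes", call. = FALSE)
  feats <- do.call(rbind, purrr::map(patches$pixels, tile_features))
  withr::with_seed(seed, {
    n <- nrow(feats)
    holdout <- sample.int(n, max(1L, round(0.2 * n)))
    rf <- randomForest::randomForest(x = feats[-holdout, , drop = FALSE],
                                     y = y[-holdout], ntree = n_trees)
    acc <- mean(stats::predict(rf, feats[holdout, , drop = FALSE]) == y[holdout])
  })
  structure(list(forest = rf, feature_names = colnames(feats),
                 classes = levels(y), holdout_accuracy = acc),
            class = "compartment_classifier")
}

#' Classify tissue compartments and compute area fractions
#'
#' Tiles the raster (stride = tile size), predicts each tile's compartment
#' with the trained forest, and converts tile counts to areas via the
#' calibration. `percent_adipose` is computed over the three tissue labels
#' (adipose, stroma, epithelium); any `background` label is excluded from
#' the denominator.
#'
#' @param raster A [calibrated_raster()].
#' @param model A [train_compartment_classifier()] fit.
#' @param tile_px Tile side length in pixels (default 64).
#' @return List of class `compartment_map`: `label_grid` (tile-level factor
#'   matrix), `tile_px`, `areas` (tibble label / area_um2 / percent over
#'   tissue labels), `percent_adipose`.
#' @export
classify_compartments <- function(raster, model, tile_px = 64) {
  stopifnot(inherits(raster, "calibrated_raster"))
  if (!inherits(model, "compartment_classifier"))
    stop("model must be a trained compartment_classifier", call. = FALSE)
  px <- raster$pixels; mpp <- raster$microns_per_pixel
  nr <- dim(px)[1]; nc <- dim(px)[2]
  rows <- seq(1, nr, by = tile_px); cols <- seq(1, nc, by = tile_px)
  grid <- expand.grid(r = rows, c = cols)
  feats <- t(apply(grid, 1, function(g) {
    r1 <- min(g[1] + tile_px - 1L, nr); c1 <- min(g[2] + tile_px - 1L, nc)
    tile <- if (length(dim(px)) == 3) px[g[1]:r1, g[2]:c1, , drop = FALSE]
            else px[g[1]:r1, g[2]:c1, drop = FALSE]
    tile_features(tile)
  }))
  pred <- stats::predict(model$forest, feats)
  lab <- matrix(as.character(pred), length(rows), length(cols))
  npix <- outer(pmin(rows + tile_px - 1L, nr) - rows + 1L,
                pmin(cols + tile_px - 1L, nc) - cols + 1L)
  areas <- tibble::tibble(label = as.vector(lab),
                          area_um2 = as.vector(npix) * mpp^2) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(area_um2 = sum(.data$area_um2), .groups = "drop")
  tissue <- dplyr::filter(areas, .data$label %in%
                            c("adipose", "stroma", "epithelium"))
  tot <- sum(tissue$area_um2)
  areas <- dplyr::mutate(areas, percent = ifelse(
    .data$label %in% tissue$label, 100 * .data$area_um2 / tot, NA_real_))
  pa <- areas$percent[areas$label == "adipose"]
  structure(list(label_grid = lab, tile_px = tile_px, areas = areas,
                 percent_adipose = if (length(pa)) pa else 0),
            class = "compartment_map")
}

#' @export
print.compartment_map <- function(x, ...) {
  cat("Compartment map (", nrow(x$label_grid), "x", ncol(x$label_grid),
      " tiles of ", x$tile_px, " px)\n", sep = "")
  print(x$areas)
  invisible(x)
}
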