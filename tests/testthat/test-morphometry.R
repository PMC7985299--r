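# Segmentation and 18-chord measurement against analytic and generator truth.

test_that("rasterized circle measures 100 um in every chord", {
  ras <- shape_raster(ngon(c(80, 80), 50), mpp = 0.5)
  obj <- measure_adipocytes(ras)
  expect_equal(nrow(obj), 1L)
  ch <- obj$chords_um[[1]]
  expect_true(all(abs(ch - 100) / 100 < 0.01))
  expect_equal(obj$median_diameter_um, 100, tolerance = 0.01)
  expect_gt(obj$circularity, 0.85)
  expect_gt(obj$regularity, 0.98)
  expect_true(obj$qc_pass)
})

test_that("rasterized ellipse chords match the analytic formula", {
  ras <- shape_raster(ellipse_poly(c(80, 60), 60, 30), mpp = 0.5)
  obj <- measure_adipocytes(ras)
  angles <- adiposize:::chord_angles_18()
  oracle <- 2 * 60 * 30 / sqrt(60^2 * sin(angles)^2 + 30^2 * cos(angles)^2)
  expect_true(all(abs(obj$chords_um[[1]] - oracle) / oracle < 0.01))
  expect_equal(obj$median_diameter_um,
               adiposize:::median_chord(oracle), tolerance = 0.01)
})

test_that("rasterized square chords match plane geometry", {
  ras <- shape_raster(square_poly(c(70, 70), 80), mpp = 0.5)
  obj <- measure_adipocytes(ras)
  ch <- obj$chords_um[[1]]
  expect_equal(ch[1], 80, tolerance = 0.01 * 80)
  expect_equal(ch[5], 80 / cos(40 * pi / 180), tolerance = 0.01 * 104.4)
})

test_that("fully stained canvas yields zero objects", {
  dark <- calibrated_raster(array(0.3, dim = c(64, 64, 3)), 1)
  expect_warning(out <- segment_vacuoles(dark), "uniform")
  expect_equal(nrow(out), 0L)
  # and with a fixed threshold, still nothing bright
  out2 <- segment_vacuoles(dark, segmentation_params(luminance_threshold = 0.5))
  expect_equal(nrow(out2), 0L)
})

test_that("duct exclusion drops objects within 500 um of the duct mask", {
  # circle centred 150 um from a duct stripe: inside the exclusion zone
  poly <- ngon(c(150, 100), 40)
  ras <- shape_raster(poly, mpp = 1, pad_um = 60)
  duct <- matrix(FALSE, nrow(ras$pixels), ncol(ras$pixels))
  duct[, 1:5] <- TRUE                    # duct at the left edge
  none <- segment_vacuoles(ras, segmentation_params(exclude_border = FALSE),
                           duct_mask = duct)
  expect_equal(nrow(none), 0L)
  near <- segment_vacuoles(ras, segmentation_params(exclude_border = FALSE,
                                                    duct_exclusion_um = 50),
                           duct_mask = duct)
  expect_equal(nrow(near), 1L)
})

test_that("mask shape mismatch is a validation error", {
  ras <- shape_raster(ngon(c(60, 60), 30), mpp = 1)
  expect_error(segment_vacuoles(ras, roi_mask = matrix(TRUE, 2, 2)),
               "dimensions")
})

test_that("segmentation recovers generator cells with accurate measurements", {
  sp <- adipo_image_spec(width_px = 1000, height_px = 1000, n_cells = 25,
                         seed = 9)
  g <- generate_adipose_image(sp)
  obj <- measure_adipocytes(calibrated_raster(g$image, g$microns_per_pixel))
  expect_equal(nrow(obj), 25L)
  tr <- g$objects
  match_idx <- vapply(seq_len(nrow(obj)), function(i) {
    which.min((tr$centroid_x_um - obj$centroid_x_um[i])^2 +
              (tr$centroid_y_um - obj$centroid_y_um[i])^2)
  }, integer(1))
  expect_equal(sort(match_idx), 1:25)    # one-to-one recovery
  big <- tr$true_median_diameter_um[match_idx] >= 40
  d_err <- abs(obj$median_diameter_um - tr$true_median_diameter_um[match_idx]) /
    tr$true_median_diameter_um[match_idx]
  a_err <- abs(obj$area_um2 - tr$true_area_um2[match_idx]) /
    tr$true_area_um2[match_idx]
  expect_true(all(d_err[big] < 0.02))
  expect_true(all(a_err[big] < 0.02))
  # centroids within one pixel of truth
  expect_true(all(sqrt((obj$centroid_x_um - tr$centroid_x_um[match_idx])^2 +
                       (obj$centroid_y_um - tr$centroid_y_um[match_idx])^2) <=
                  g$microns_per_pixel))
})

test_that("measurements are exactly scale-equivariant in the calibration", {
  poly <- ellipse_poly(c(80, 60), 55, 40)
  r1 <- shape_raster(poly, mpp = 1)
  o1 <- measure_adipocytes(r1)
  r2 <- calibrated_raster(r1$pixels, 3)   # same pixels, 3x the calibration
  o2 <- measure_adipocytes(r2)
  expect_equal(o2$median_diameter_um, 3 * o1$median_diameter_um)
  expect_equal(o2$area_um2, 9 * o1$area_um2)
  expect_equal(o2$circularity, o1$circularity)
  expect_equal(o2$regularity, o1$regularity)
})

test_that("rotating the image by 90 degrees moves medians by < 2%", {
  sp <- adipo_image_spec(width_px = 700, height_px = 700, n_cells = 12, seed = 31)
  g <- generate_adipose_image(sp)
  o1 <- measure_adipocytes(calibrated_raster(g$image, 0.5))
  rot <- array(0, dim = c(dim(g$image)[2], dim(g$image)[1], 3))
  for (k in 1:3) rot[, , k] <- t(g$image[dim(g$image)[1]:1, , k])
  o2 <- measure_adipocytes(calibrated_raster(rot, 0.5))
  expect_equal(nrow(o2), nrow(o1))
  m1 <- sort(o1$median_diameter_um); m2 <- sort(o2$median_diameter_um)
  expect_true(all(abs(m1 - m2) / m1 < 0.02))
})

test_that("QC rejects small, crescent and unmeasurable objects with reasons", {
  params <- segmentation_params()
  # 25 um circle: below the 30 um minimum diameter
  small <- measure_objects(tibble::tibble(contour = list(ngon(c(40, 40), 12.5))))
  small_qc <- qc_filter(small, params)
  expect_false(small_qc$qc_pass)
  expect_match(small_qc$qc_reason, "min_diameter")
  # crescent: fails circularity and regularity at the defaults
  cres <- measure_objects(tibble::tibble(
    contour = list(adiposize:::crescent_polygon(c(100, 100), 40))))
  expect_lt(cres$circularity, 0.6)
  cres_qc <- qc_filter(cres, params)
  expect_false(cres_qc$qc_pass)
  expect_match(cres_qc$qc_reason, "min_circularity|min_regularity")
  # perfect 100 um circle: kept
  good <- qc_filter(measure_objects(tibble::tibble(
    contour = list(ngon(c(80, 80), 50)))), params)
  expect_true(good$qc_pass)
  expect_identical(good$qc_reason, "")
  # empty input passes through
  empty <- qc_filter(measure_objects(adiposize:::empty_segmentation()), params)
  expect_equal(nrow(empty), 0L)
})

test_that("generated crescent artifacts are rejected by default QC", {
  sp <- adipo_image_spec(width_px = 900, height_px = 900, n_cells = 10,
                         artifact_fraction = 0.4, seed = 17)
  g <- generate_adipose_image(sp)
  meas <- measure_objects(tibble::tibble(contour = g$objects$polygon)) |>
    qc_filter()
  expect_true(all(!meas$qc_pass[g$objects$is_artifact]))
  expect_true(all(meas$qc_pass[!g$objects$is_artifact & !g$objects$is_debris]))
})

test_that("patient summaries use rank-interpolated 75th percentiles", {
  obj <- tibble::tibble(patient_id = "p1",
                        median_diameter_um = c(40, 50, 60, 70),
                        area_um2 = c(1000, 2000, 3000, 4000),
                        qc_pass = TRUE)
  prof <- summarize_patients(obj)
  expect_equal(prof$area_p75_um2, 3250)
  expect_equal(prof$diameter_p75_um, 62.5)
  expect_equal(prof$mean_area_um2, 2500)

  same <- tibble::tibble(median_diameter_um = rep(80, 6),
                         area_um2 = rep(5000, 6), qc_pass = TRUE)
  expect_equal(summarize_patients(same, "p2")$area_p75_um2, 5000)
})

test_that("p75 matches the lognormal quantile at n = 10,000", {
  set.seed(42)
  areas <- rlnorm(10000, meanlog = 8.7, sdlog = 0.3)
  obj <- tibble::tibble(median_diameter_um = sqrt(areas), area_um2 = areas,
                        qc_pass = TRUE)
  prof <- summarize_patients(obj, "p")
  expected <- exp(8.7 + 0.3 * qnorm(0.75))
  expect_equal(prof$area_p75_um2, expected, tolerance = 0.01)
})

test_that("p75 never decreases when a larger object is added", {
  set.seed(7)
  for (rep in 1:20) {
    areas <- rlnorm(sample(5:50, 1), 8.5, 0.4)
    obj <- tibble::tibble(median_diameter_um = sqrt(areas), area_um2 = areas,
                          qc_pass = TRUE)
    p0 <- summarize_patients(obj, "p")$area_p75_um2
    bigger <- p0 * runif(1, 1.01, 3)
    obj2 <- dplyr::bind_rows(obj, tibble::tibble(
      median_diameter_um = sqrt(bigger), area_um2 = bigger, qc_pass = TRUE))
    expect_gte(summarize_patients(obj2, "p")$area_p75_um2, p0)
  }
})

test_that("a patient with zero kept objects is flagged not assessable", {
  obj <- tibble::tibble(patient_id = c("a", "b"),
                        median_diameter_um = c(80, 20),
                        area_um2 = c(5000, 300),
                        qc_pass = c(TRUE, FALSE))
  expect_warning(prof <- summarize_patients(obj), "not assessable.*b")
  expect_equal(prof$patient_id, "a")
})
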