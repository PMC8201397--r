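test_that("panel calibration applies the mean gain and clips to [0, 1]", {
  b <- uniform_raster(0.10, band = "reflectance")
  expect_equal(calibrate_reflectance(b, 0.5, 0.25, 0.25)$values[1, 1], 0.2)
  # asymmetric bracketing observations: gain = 0.5 / mean(0.25, 0.50)
  b2 <- uniform_raster(0.375, band = "reflectance")
  expect_equal(calibrate_reflectance(b2, 0.5, 0.25, 0.50)$values[1, 1], 0.5)
  expect_error(calibrate_reflectance(b, 0.5, 0.25, 0), "positive")
  expect_error(calibrate_reflectance(b, 1.5, 0.25, 0.25), "panel_known")
  # clipping and mask preservation
  v <- matrix(c(0.9, NA, 0.1, 0.2), 2, 2)
  r <- field_raster(v, pixel_size = 0.5, band = "reflectance")
  out <- calibrate_reflectance(r, 0.5, 0.2, 0.2)  # gain 2.5
  expect_equal(out$values[1, 1], 1)        # 2.25 clipped
  expect_true(is.na(out$values[2, 1]))
})

test_that("calibration is linear below the clip", {
  set.seed(4)
  v <- matrix(runif(24, 0, 0.2), 4, 6)
  r <- field_raster(v, pixel_size = 1, band = "reflectance")
  ra <- field_raster(2 * v, pixel_size = 1, band = "reflectance")
  c1 <- calibrate_reflectance(r, 0.5, 0.4, 0.4)
  c2 <- calibrate_reflectance(ra, 0.5, 0.4, 0.4)
  expect_equal(c2$values, 2 * c1$values, tolerance = 1e-12)
})

test_that("NDVI arithmetic, bounds and masking", {
  red <- uniform_raster(0.2, band = "reflectance")
  nir <- uniform_raster(0.6, band = "reflectance")
  expect_equal(compute_ndvi(red, nir)$values[1, 1], 0.5)
  expect_equal(compute_ndvi(nir, nir)$values[2, 2], 0)  # NIR = Red
  expect_equal(compute_ndvi(uniform_raster(0, band = "reflectance"),
                            uniform_raster(1, band = "reflectance"))$values[1, 1],
               1)                                        # upper bound attained
  # zero denominator and input masks propagate
  rv <- matrix(c(0, 0.2, NA, 0.3), 2, 2)
  nv <- matrix(c(0, 0.6, 0.5, 0.6), 2, 2)
  out <- compute_ndvi(field_raster(rv, pixel_size = 1, band = "reflectance"),
                      field_raster(nv, pixel_size = 1, band = "reflectance"))
  expect_true(is.na(out$values[1, 1]))
  expect_true(is.na(out$values[1, 2]))
  expect_error(compute_ndvi(red, uniform_raster(0.6, nr = 5,
                                                band = "reflectance")),
               "co-registration")
  # range invariant on random reflectances
  set.seed(11)
  a <- field_raster(matrix(runif(100), 10), pixel_size = 1,
                    band = "reflectance")
  b <- field_raster(matrix(runif(100), 10), pixel_size = 1,
                    band = "reflectance")
  nd <- compute_ndvi(a, b)$values
  expect_true(all(nd >= -1 & nd <= 1, na.rm = TRUE))
})

test_that("excess-green segmentation labels vegetation and reports cover", {
  g <- function(v) uniform_raster(v, nr = 4, nc = 4, band = "rgb")
  veg <- segment_vegetation(g(0), g(1), g(0))       # pure green, ExG = 2
  expect_true(all(veg$values == 1))
  gray <- segment_vegetation(g(0.5), g(0.5), g(0.5))  # ExG = 0, not > 0
  expect_true(all(gray$values == 0))
  # half pure green, half gray: cover fraction is exactly 0.5 by pixel count
  rv <- matrix(rep(c(0, 0.5), each = 8), 4, 4)
  gv <- matrix(rep(c(1, 0.5), each = 8), 4, 4)
  out <- segment_vegetation(field_raster(rv, pixel_size = 0.5, band = "rgb"),
                            field_raster(gv, pixel_size = 0.5, band = "rgb"),
                            field_raster(rv, pixel_size = 0.5, band = "rgb"))
  expect_equal(mean(out$values), 0.5)
  expect_true(all(out$values %in% c(0, 1)))
  # fully masked image errors
  na_r <- field_raster(matrix(NA_real_, 2, 2), pixel_size = 1, band = "rgb")
  expect_error(segment_vegetation(na_r, na_r, na_r), "masked")
})

test_that("automatic threshold agrees with an independent Otsu implementation", {
  skip_if_not_installed("EBImage")
  set.seed(21)
  # bimodal green channel; red = blue = 0, so ExG = 2 * green
  green_vals <- c(rnorm(4000, 0.25, 0.05), rnorm(4000, 0.75, 0.06))
  green_vals <- pmin(pmax(green_vals, 0), 1)
  red <- field_raster(matrix(0, 80, 100), pixel_size = 1, band = "rgb")
  green <- field_raster(matrix(green_vals, 80, 100), pixel_size = 1,
                        band = "rgb")
  out <- segment_vegetation(red, green, red, method = "automatic")
  t_pkg <- attr(out, "threshold")
  sc <- 2 * green$values
  # oracle: EBImage's Otsu on the same scores rescaled to [0, 1]
  rng <- range(sc)
  t_eb <- EBImage::otsu(EBImage::Image((sc - rng[1]) / diff(rng)),
                        range = c(0, 1), levels = 256)
  t_eb <- rng[1] + t_eb * diff(rng)
  # between well-separated modes the histogram valley is flat, so exact
  # cut points may differ; both must induce the same segmentation and
  # fall between the modes
  expect_equal(mean(sc > t_pkg), mean(sc > t_eb), tolerance = 1e-3)
  expect_gt(t_pkg, 0.7); expect_lt(t_pkg, 1.3)
  expect_gt(t_eb, 0.7); expect_lt(t_eb, 1.3)
  expect_equal(out$values, matrix(as.numeric(sc > t_pkg), 80, 100))
})

test_that("canopy height subtracts ground and clamps negatives to zero", {
  dsm <- uniform_raster(103.2, band = "elevation")
  gnd <- uniform_raster(103.2, band = "elevation")
  expect_true(all(compute_height(dsm, gnd)$values == 0))
  dsm2 <- uniform_raster(103.5, band = "elevation")
  expect_equal(compute_height(dsm2, gnd)$values[1, 1], 0.3)
  # per-pixel clamp rule checked against a brute-force loop
  set.seed(9)
  d <- matrix(100 + rnorm(30, 0, 0.2), 5, 6)
  g2 <- matrix(100, 5, 6); d[2, 2] <- NA
  h <- compute_height(field_raster(d, pixel_size = 1, band = "elevation"),
                      field_raster(g2, pixel_size = 1, band = "elevation"))
  for (i in 1:5) for (j in 1:6) {
    want <- if (is.na(d[i, j])) NA_real_ else max(d[i, j] - 100, 0)
    expect_identical(h$values[i, j], want)
  }
  expect_true(all(h$values >= 0, na.rm = TRUE))
  expect_error(compute_height(dsm, uniform_raster(1, nr = 9,
                                                  band = "elevation")),
               "co-registration")
})

test_that("index stacks enforce unique names, co-registration and exclusions", {
  r <- uniform_raster(0.5)
  nms <- c("C_Feb.15", "C_Mar.14", "C_Apr.12", "H_Feb.15", "H_Mar.14",
           "H_Apr.12", "N_Mar.14", "N_Apr.12")
  layers <- setNames(rep(list(r), 8), nms)
  s <- build_index_stack(layers, exclude = "H_Feb.15")
  expect_equal(s$m, 7)  # the seven-variable candidate set
  expect_false("H_Feb.15" %in% names(s$layers))
  expect_equal(build_index_stack(layers[1:3])$m, 3)
  expect_error(build_index_stack(setNames(list(r, r), c("a", "a"))),
               "duplicate")
  expect_error(build_index_stack(list(a = r, b = uniform_raster(1, nr = 7))),
               "co-registration")
})
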