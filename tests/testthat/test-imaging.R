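test_that("preprocess is a fixed point on uniform images and reduces noise", {
  flat <- matrix(0.5, 64, 64)
  expect_equal(preprocess(flat), flat)
  # pure-noise background: sigma strictly reduced by the median filter
  set.seed(20)
  noisy <- pmin(pmax(matrix(rnorm(128 * 128, 0.3, 10 / 255), 128, 128), 0), 1)
  expect_lt(sd(preprocess(noisy)), sd(noisy))
  # grayscale passes through channel conversion unchanged (no filtering)
  expect_equal(preprocess(noisy, median_radius = 0), noisy)
  expect_error(preprocess(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("preprocess collapses colour images to one channel", {
  arr <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  g <- preprocess(arr, median_radius = 0)
  expect_true(is.matrix(g))
  expect_equal(dim(g), c(32, 32))
  img <- EBImage::Image(arr, colormode = "Color")
  expect_equal(dim(preprocess(img, median_radius = 0)), c(32, 32))
})

test_that("segmentation recovers the rendered egg's area and rejects blanks", {
  egg <- render_egg(synthetic_egg_spec(180, 140, taper = 0.1, seed = 21))
  seg <- segment_egg(egg$raster)
  expect_lt(abs(seg$area - egg$truth$area) / egg$truth$area, 0.005)
  expect_error(segment_egg(matrix(0.4, 50, 50)), "no egg detected")
})

test_that("segmentation keeps only the largest component and fills holes", {
  img <- matrix(0.1, 200, 200)
  img[40:139, 40:139] <- 0.9   # 100x100 = 10,000 px blob
  img[80:99, 80:99] <- 0.1     # hole, must be filled
  img[170:189, 170:189] <- 0.9 # 400 px distractor
  seg <- segment_egg(img)
  expect_equal(seg$area, 10000L)
  expect_false(seg$mask[180, 180])
  expect_equal(unname(scan_extents(seg$mask)), c(100, 100))
})

test_that("segmentation warns when the egg touches the border", {
  img <- matrix(0.1, 80, 80)
  img[1:40, 30:50] <- 0.9
  expect_warning(segment_egg(img), "border")
})

test_that("axis measurement is accurate and rotation invariant", {
  # axis-aligned tapered egg, 200 x 150 px
  ax <- measure_axes(render_egg(synthetic_egg_spec(200, 150, seed = 22))$mask)
  expect_equal(ax$length_px, 200, tolerance = 1 / 200)
  expect_equal(ax$breadth_px, 150, tolerance = 1 / 150)
  # same shape at 37 degrees
  ax37 <- measure_axes(
    render_egg(synthetic_egg_spec(200, 150, orientation = 37, seed = 22))$mask)
  expect_lt(abs(ax37$length_px - 200), 1)
  expect_lt(abs(ax37$breadth_px - 150), 1)
  expect_equal(ax37$orientation, 37, tolerance = 1 / 37)
  # circle: both extents equal the diameter
  axc <- measure_axes(render_egg(synthetic_egg_spec(120, 120, seed = 23))$mask)
  expect_equal(axc$length_px, 120, tolerance = 1 / 120)
  expect_equal(axc$breadth_px, 120, tolerance = 1 / 120)
  expect_gte(ax$length_px, ax$breadth_px)
  expect_error(measure_axes(matrix(FALSE, 5, 5)), "no foreground")
})

test_that("measured length never falls below measured breadth", {
  set.seed(24)
  for (i in 1:8) {
    L <- round(runif(1, 100, 220)); B <- round(runif(1, 80, L))
    ax <- measure_axes(render_egg(synthetic_egg_spec(
      L, B, taper = runif(1, 0, 0.3), orientation = runif(1, 0, 180),
      seed = i))$mask)
    expect_gte(ax$length_px, ax$breadth_px)
  }
})

test_that("calibration scale is the mm/px ratio and round-trips", {
  expect_equal(calibrate_scale(30, 100)$mm_per_px, 0.3)
  expect_equal(calibrate_scale(45.60, 152)$mm_per_px, 0.3)
  expect_equal(200 * calibrate_scale(60, 200)$mm_per_px, 60)
  expect_equal(calibrate_scale(30, 100)$source, "reference-object")
  expect_error(calibrate_scale(0, 10), "positive")
})

test_that("measure_image recovers metric axes within 1% under noise", {
  sp <- synthetic_egg_spec(405, 304, taper = 0.15, orientation = 63,
                           noise_sigma = 10, illumination_gradient = 15,
                           seed = 25)
  egg <- render_egg(sp)
  m <- measure_image(egg$raster, calibration_profile(0.15), weight = 70.6)
  expect_lt(abs(m$length - 405 * 0.15) / (405 * 0.15), 0.01)
  expect_lt(abs(m$breadth - 304 * 0.15) / (304 * 0.15), 0.01)
  # circle: downstream shape index is 100 within a pixel's worth
  circ <- render_egg(synthetic_egg_spec(150, 150, noise_sigma = 5, seed = 26))
  mc <- measure_image(circ$raster, calibration_profile(0.3), weight = 60)
  expect_equal(shape_index(mc$length, mc$breadth), 100, tolerance = 1 / 150)
  expect_error(measure_image(matrix(0.2, 60, 60), calibration_profile(0.2), 60),
               "no egg detected")
})

test_that("doubling the rendering resolution leaves metric axes within 1%", {
  egg1 <- render_egg(synthetic_egg_spec(200, 150, taper = 0.1,
                                        orientation = 20, seed = 27))
  egg2 <- render_egg(synthetic_egg_spec(400, 300, taper = 0.1,
                                        orientation = 20, seed = 27))
  m1 <- measure_image(egg1$raster, calibration_profile(0.3), weight = 60)
  m2 <- measure_image(egg2$raster, calibration_profile(0.15), weight = 60)
  expect_equal(m1$length, m2$length, tolerance = 0.01)
  expect_equal(m1$breadth, m2$breadth, tolerance = 0.01)
})
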