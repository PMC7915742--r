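test_that("to_suv divides by dose per kilogram and is linear", {
  img <- pet_image(array(6.0, c(4, 4, 4)), spacing = 2)
  expect_equal(to_suv(img, suv_calibration(210, 70))$values[1], 2.0)
  expect_identical(to_suv(img, suv_calibration(70, 70))$values, img$values)
  c3 <- img; c3$values <- 3 * c3$values
  expect_equal(to_suv(c3, suv_calibration(210, 70))$values,
               3 * to_suv(img, suv_calibration(210, 70))$values)
  expect_equal(to_suv(img, suv_calibration(210, 70))$units, "SUV")
  expect_error(suv_calibration(0, 70), "injected_dose")
  expect_error(suv_calibration(210, -1), "body_weight")
})

test_that("sphere_mask volumes match the closed form", {
  img <- pet_image(array(1, c(48, 48, 48)), spacing = 2)
  ctr <- c(47, 47, 47)
  s30 <- sphere_mask(img, ctr, 30)
  expect_equal(attr(s30, "analytic_volume_ml"), 14.137, tolerance = 1e-3)
  expect_lt(abs(attr(s30, "realized_volume_ml") - 14.137) / 14.137, 0.05)
  s10 <- sphere_mask(img, ctr, 10)
  expect_equal(attr(s10, "analytic_volume_ml"), 0.5236, tolerance = 1e-3)
  s40 <- sphere_mask(img, ctr, 40)
  expect_equal(attr(s40, "analytic_volume_ml"), 33.51, tolerance = 1e-2)

  # sub-voxel sphere centered on a voxel center: exactly 1 voxel
  s1 <- sphere_mask(img, c(48, 48, 48), 1.5)
  expect_identical(sum(s1$mask), 1L)

  expect_error(sphere_mask(img, c(500, 500, 500), 10), "outside")
})

test_that("realized sphere volume converges to analytic as spacing shrinks", {
  vol_err <- vapply(c(2, 1, 0.5), function(sp) {
    n <- round(44 / sp)
    img <- pet_image(array(1, c(n, n, n)), spacing = sp)
    m <- sphere_mask(img, rep((n - 1) * sp / 2, 3), 30)
    abs(attr(m, "realized_volume_ml") - attr(m, "analytic_volume_ml")) /
      attr(m, "analytic_volume_ml")
  }, numeric(1))
  expect_true(all(diff(vol_err) < 0))
  expect_lt(vol_err[3], 0.01)
})

test_that("auto_contour_tbr recovers the lesion and respects the threshold", {
  ps <- phantom_spec(shape = c(48, 48, 48), tumor_radius = 12,
                     tbr_contrast = 2.0, texture_amplitude = 0, psf_fwhm = 0)
  ph <- make_phantom(ps, seed = 1)
  bg <- background_sphere(ph, ps$tumor_center, 30)

  contour <- auto_contour_tbr(ph, bg, 1.6)
  expect_identical(contour$mask, attr(ph, "true_tumor_mask"))

  # contrast below the threshold: nothing to contour
  ps15 <- phantom_spec(shape = c(48, 48, 48), tumor_radius = 12,
                       tbr_contrast = 1.5, texture_amplitude = 0,
                       psf_fwhm = 0)
  ph15 <- make_phantom(ps15, seed = 1)
  bg15 <- background_sphere(ph15, ps15$tumor_center, 30)
  expect_error(auto_contour_tbr(ph15, bg15, 1.6), "no tumor detected")

  # uniform image: no voxel exceeds 1.6 x mean
  unif <- pet_image(array(1, c(20, 20, 20)), spacing = 2)
  bgu <- sphere_mask(unif, c(19, 19, 19), 16, label = "background_sphere")
  expect_error(auto_contour_tbr(unif, bgu, 1.6), "no tumor detected")

  # invariant to positive rescaling (the threshold is a ratio)
  sc <- ph; sc$values <- 17.3 * sc$values
  expect_identical(auto_contour_tbr(sc, bg, 1.6)$mask, contour$mask)
})

test_that("auto_contour_tbr keeps the component containing the maximum", {
  img <- pet_image(array(1, c(30, 30, 30)), spacing = 2)
  # large dim blob and small bright blob, disconnected
  big <- petrepeat:::sphere_indicator(c(30, 30, 30), c(2, 2, 2), c(0, 0, 0),
                          c(16, 16, 16), 10)
  small <- petrepeat:::sphere_indicator(c(30, 30, 30), c(2, 2, 2), c(0, 0, 0),
                            c(46, 46, 46), 5)
  img$values[big] <- 2.0
  img$values[small] <- 3.0
  bg <- sphere_mask(img, c(46, 12, 12), 14, label = "background_sphere")
  contour <- auto_contour_tbr(img, bg, 1.6)
  expect_identical(contour$mask, small)
})

test_that("tumor_sphere_series shares one center and nests", {
  ps <- phantom_spec(shape = c(48, 48, 48), tumor_radius = 14,
                     texture_amplitude = 0.3, psf_fwhm = 2)
  ph <- make_phantom(ps, seed = 3)
  bg <- background_sphere(ph, ps$tumor_center, 30)
  tumor <- auto_contour_tbr(ph, bg, 1.6)
  series <- tumor_sphere_series(ph, tumor, diameters = c(10, 16, 24, 30))
  centers <- unique(lapply(series, attr, "center_mm"))
  expect_length(centers, 1L)
  # the center voxel is the in-tumor argmax
  vals <- ph$values; vals[!tumor$mask] <- -Inf
  ijk <- arrayInd(which.max(vals), dim(ph$values))[1, ]
  expect_equal(centers[[1]], (ijk - 1) * ph$spacing)
  # monotone nesting with diameter
  for (i in 1:3) {
    expect_true(all(series[[i]]$mask <= series[[i + 1]]$mask))
  }
})

test_that("tie at the maximum breaks deterministically with a warning", {
  img <- pet_image(array(1, c(12, 12, 12)), spacing = 2)
  img$values[5, 5, 5] <- 4
  img$values[8, 8, 8] <- 4
  tumor <- voi_mask(img$values > 2, label = "tumor_contour")
  expect_warning(series <- tumor_sphere_series(img, tumor, diameters = 6),
                 "tie")
  expect_equal(attr(series[[1]], "center_mm"), c(4, 4, 4) * 2)
})
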