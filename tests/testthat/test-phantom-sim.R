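test_that("make_phantom builds the stated piecewise world", {
  # no texture, no blur: exactly two levels with the stated contrast
  ps <- phantom_spec(shape = c(40, 40, 40), tumor_radius = 12,
                     tbr_contrast = 2.0, texture_amplitude = 0,
                     psf_fwhm = 0)
  ph <- make_phantom(ps, seed = 1)
  tumor <- attr(ph, "true_tumor_mask")
  expect_setequal(unique(as.numeric(ph$values)), c(1.0, 2.0))
  expect_equal(mean(ph$values[tumor]) / mean(ph$values[!tumor]), 2.0)

  # closed-form sphere volume: r = 15 mm -> 14.14 mL; voxel-center count
  # approximates it on a 2 mm grid
  ps15 <- phantom_spec(shape = c(48, 48, 48), tumor_radius = 15,
                       texture_amplitude = 0, psf_fwhm = 0)
  ph15 <- make_phantom(ps15, seed = 1)
  vol_true <- 4 / 3 * pi * 15^3 / 1000
  expect_equal(vol_true, 14.137, tolerance = 1e-4)
  vol_vox <- sum(attr(ph15, "true_tumor_mask")) * voxel_volume(ph15) / 1000
  expect_lt(abs(vol_vox - vol_true) / vol_true, 0.05)

  # texture modulates the tumor but leaves the background untouched
  pst <- phantom_spec(shape = c(40, 40, 40), tumor_radius = 12,
                      texture_amplitude = 0.3, psf_fwhm = 0)
  pht <- make_phantom(pst, seed = 2)
  tum <- attr(pht, "true_tumor_mask")
  expect_gt(stats::sd(pht$values[tum]), 0)
  expect_equal(unique(as.numeric(pht$values[!tum])), 1.0)
  # same seed reproduces the field bitwise
  expect_identical(pht$values, make_phantom(pst, seed = 2)$values)

  expect_error(
    make_phantom(phantom_spec(shape = c(20, 20, 20),
                              tumor_center = c(38, 19, 19) * 2,
                              tumor_radius = 10), seed = 1),
    "does not fit")
})

test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(tbr_contrast = 0.9), "tbr_contrast")
  expect_error(phantom_spec(texture_amplitude = 1.0), "texture_amplitude")
  expect_error(phantom_spec(psf_fwhm = -1), "psf_fwhm")
})

test_that("simulate_counts is Poisson in mean and variance", {
  ps <- phantom_spec(shape = c(12, 12, 12), tumor_radius = 6,
                     texture_amplitude = 0, psf_fwhm = 0,
                     tumor_center = c(11, 11, 11))
  ph <- make_phantom(ps, seed = 1)

  zero <- pet_image(array(0, c(4, 4, 4)), spacing = 2)
  expect_true(all(simulate_counts(zero, 100, seed = 1)$values == 0))

  # law of large numbers: counts/exposure converges to the map
  big <- simulate_counts(ph, exposure = 1e6, seed = 3)
  expect_lt(max(abs(big$values / 1e6 - ph$values) / ph$values), 0.02)

  # per-voxel sample variance tracks the mean across seeds
  lam <- 7.3
  one <- pet_image(array(lam, c(10, 10, 10)), spacing = 2)
  draws <- simulate_counts(one, exposure = 1, seed = 4)$values
  expect_equal(mean(draws), lam, tolerance = 0.05)
  expect_equal(stats::var(as.numeric(draws)), lam, tolerance = 0.1)

  bad <- pet_image(array(1, c(2, 2, 2)), spacing = 2)
  bad$values[1] <- Inf
  expect_error(simulate_counts(bad, 1, seed = 1), "non-finite")
})

test_that("split_events conserves counts exactly and halves are independent", {
  lam <- 100
  img <- pet_image(array(lam, c(22, 22, 22)), spacing = 2)  # >10^4 voxels
  cnt <- simulate_counts(img, exposure = 1, seed = 5)
  h <- split_events(cnt, seed = 6)
  expect_true(all(h$a$values + h$b$values == cnt$values))
  expect_true(all(h$a$values >= 0) && all(h$b$values >= 0))

  # zero counts split to (0, 0)
  zero <- pet_image(array(0, c(3, 3, 3)), spacing = 2)
  hz <- split_events(simulate_counts(zero, 1, seed = 1), seed = 1)
  expect_true(all(hz$a$values == 0) && all(hz$b$values == 0))

  # independence: deviations of the halves are uncorrelated over >10^4 draws
  r <- stats::cor(as.numeric(h$a$values), as.numeric(h$b$values))
  expect_lt(abs(r), 0.05)

  # deterministic given the seed; alternate method also conserves
  h2 <- split_events(cnt, seed = 6)
  expect_identical(h$a$values, h2$a$values)
  ha <- split_events(cnt, method = "alternate")
  expect_true(all(ha$a$values + ha$b$values == cnt$values))
  expect_true(all(abs(ha$a$values - ha$b$values) <= 1))
})

test_that("each half is Poisson with half the mean", {
  lam <- 100
  img <- pet_image(array(lam, c(22, 22, 22)), spacing = 2)
  h <- split_events(simulate_counts(img, 1, seed = 7), seed = 8)
  x <- as.numeric(h$a$values)
  expect_equal(mean(x), lam / 2, tolerance = 0.02)
  expect_equal(stats::var(x), lam / 2, tolerance = 0.05)
  # chi-square goodness of fit against Poisson(lam/2), 1% level
  k <- 30:70
  obs <- tabulate(factor(pmin(pmax(x, 30), 70), levels = k))
  p <- stats::dpois(k, lam / 2)
  p[1] <- stats::ppois(29, lam / 2) + p[1]
  p[length(p)] <- 1 - stats::ppois(69, lam / 2)
  keep <- p * length(x) >= 5
  chi <- sum((obs[keep] - length(x) * p[keep])^2 / (length(x) * p[keep]))
  expect_gt(stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("reconstruct_image inverts the exposure scaling", {
  img <- pet_image(array(5, c(6, 6, 6)), spacing = 2)
  cnt <- simulate_counts(img, exposure = 40, seed = 1)
  cnt$values[] <- 40  # counts all K with exposure K -> uniform 1.0
  rec <- reconstruct_image(cnt, exposure = 40)
  expect_true(all(rec$values == 1.0))
  # fwhm 0 is the identity on counts/exposure
  expect_identical(reconstruct_image(cnt, 40, post_smoothing_fwhm = 0)$values,
                   cnt$values / 40)
  # split halves reconstructed at exposure/2 are unbiased for the map
  ph <- pet_image(array(2.5, c(16, 16, 16)), spacing = 2)
  means <- replicate(20, {
    h <- split_events(simulate_counts(ph, 200, seed = sample.int(1e6, 1)),
                      seed = sample.int(1e6, 1))
    c(mean(reconstruct_image(h$a, 100)$values),
      mean(reconstruct_image(h$b, 100)$values))
  })
  expect_equal(mean(means), 2.5, tolerance = 0.01)
})

test_that("simulate_cohort is deterministic and reflects group structure", {
  spec <- cohort_spec(
    n_per_group = c(wildtype = 6L, mutant = 6L),
    volume_mean_ml = c(wildtype = 12, mutant = 3),
    volume_cv = 0.3,
    shape = c(40, 40, 40), psf_fwhm = 0, exposure = 100, seed = 11L)
  ch <- simulate_cohort(spec)
  expect_length(ch, 12L)
  man <- attr(ch, "manifest")
  expect_identical(nrow(man), 12L)
  # stated direction: wildtype tumors larger on average
  expect_gt(mean(man$true_volume_mL[man$genotype == "wildtype"]),
            mean(man$true_volume_mL[man$genotype == "mutant"]))
  # same master seed: bitwise-identical cohort
  ch2 <- simulate_cohort(spec)
  expect_identical(ch[[3]]$pair$test$values, ch2[[3]]$pair$test$values)
  expect_identical(man, attr(ch2, "manifest"))
  # extending a group must not reshuffle earlier subjects
  spec_big <- spec
  spec_big$n_per_group <- c(wildtype = 7L, mutant = 6L)
  ch3 <- simulate_cohort(spec_big)
  expect_identical(ch[[2]]$pair$test$values, ch3[[2]]$pair$test$values)

  expect_error(cohort_spec(n_per_group = c(wildtype = 1L, mutant = 5L)),
               "n >= 2")
})
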