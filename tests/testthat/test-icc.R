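test_that("icc_a1 reproduces the hand-worked two-way ANOVA", {
  m <- rbind(c(1, 2), c(3, 4), c(5, 6))
  fit <- icc_a1(m)
  expect_equal(fit$ms_r, 8)
  expect_equal(fit$ms_c, 1.5)
  expect_equal(fit$ms_e, 0)
  expect_equal(fit$icc, 8 / 9)
})

test_that("icc_a1 agrees with the explicit sums-of-squares oracle", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    k <- sample(2:4, 1)
    m <- matrix(stats::rnorm(n * k, 5, 2), n, k) +
      stats::rnorm(n, 0, runif(1, 0, 3))
    expect_equal(icc_a1(m)$icc, oracle_icc(m), tolerance = 1e-12)
  }
})

test_that("ICC has the absolute-agreement symmetries", {
  set.seed(13)
  b <- stats::rnorm(12, 10, 2)
  m <- cbind(b + stats::rnorm(12, 0, 0.5), b + stats::rnorm(12, 0, 0.5))
  r0 <- icc_a1(m)$icc
  expect_equal(icc_a1(m + 7)$icc, r0, tolerance = 1e-12)          # shift
  expect_equal(icc_a1(3.2 * m)$icc, r0, tolerance = 1e-12)        # scale
  expect_equal(icc_a1(m[, 2:1])$icc, r0, tolerance = 1e-12)       # swap
})

test_that("perfect agreement and pure noise behave as expected", {
  b <- c(1, 4, 2, 8, 5)
  perfect <- cbind(b, b)
  fit <- icc_ci(perfect)
  expect_equal(fit$icc, 1)
  expect_equal(fit$ci_high, 1)

  # Monte-Carlo null: two independent columns, large n
  set.seed(14)
  noise <- matrix(stats::rnorm(2e4), ncol = 2)
  expect_lt(abs(icc_a1(noise)$icc), 0.05)

  # all entries equal: undefined, flagged
  flat <- matrix(2, 4, 2)
  expect_true(is.nan(icc_a1(flat)$icc))
  expect_true(is.nan(icc_ci(flat)$ci_low))
})

test_that("icc_ci matches the frozen reference oracle to 1e-6", {
  orc <- utils::read.csv(test_path("fixtures", "icc_reference_oracle.csv"))
  mats <- gen_icc_matrices()
  expect_identical(nrow(orc), length(mats))
  for (i in seq_along(mats)) {
    fit <- icc_ci(mats[[i]])
    expect_equal(fit$icc, orc$icc[i], tolerance = 1e-6)
    expect_equal(fit$ci_low, orc$ci_low[i], tolerance = 1e-6)
    expect_equal(fit$ci_high, orc$ci_high[i], tolerance = 1e-6)
    # and within the printed precision of the reference's own CI output
    expect_lt(abs(fit$ci_low - orc$ci_low_pg2dp[i]), 0.006)
    expect_lt(abs(fit$ci_high - orc$ci_high_pg2dp[i]), 0.006)
  }
})

test_that("CI bounds bracket the estimate and widen at small n", {
  set.seed(15)
  width <- vapply(c(5, 50), function(n) {
    mean(replicate(40, {
      b <- stats::rnorm(n, 0, 1)
      m <- cbind(b + stats::rnorm(n, 0, 0.5), b + stats::rnorm(n, 0, 0.5))
      fit <- icc_ci(m)
      expect_lte(fit$ci_low, fit$icc)
      expect_gte(fit$ci_high, fit$icc)
      fit$ci_high - fit$ci_low
    }))
  }, numeric(1))
  expect_gt(width[1], width[2])
})

test_that("the CI-band classification reproduces the three-band rule", {
  grid <- rbind(
    # ci_low, ci_high, expected
    c(0.93, 0.99, "repeatable"),
    c(0.91, 1.00, "repeatable"),     # boundary: both limits in band
    c(0.91, 0.91, "repeatable"),
    c(0.80, 0.95, "moderate"),
    c(0.75, 0.91, "moderate"),       # boundary: lower at 0.75, upper at 0.91
    c(0.90, 0.99, "moderate"),
    c(0.50, 0.95, "not_repeatable"), # lower below 0.75
    c(0.74, 0.99, "not_repeatable"),
    c(0.80, 0.90, "not_repeatable"), # upper below 0.91
    c(-0.30, 0.50, "not_repeatable"),
    c(0.01, 0.90, "not_repeatable")
  )
  got <- classify_icc(as.numeric(grid[, 1]), as.numeric(grid[, 2]))
  expect_identical(got, grid[, 3])
  expect_identical(classify_icc(NaN, NaN), "not_repeatable")
})

test_that("icc_table drops flagged subjects pairwise and summarizes", {
  set.seed(16)
  n <- 12
  b <- stats::rnorm(n, 5, 2)
  good <- cbind(b + stats::rnorm(n, 0, 0.05), b + stats::rnorm(n, 0, 0.05))
  noisy <- matrix(stats::rnorm(2 * n), n, 2)
  flagged <- good
  flagged[3, 1] <- NaN
  test <- cbind(f_good = good[, 1], f_noisy = noisy[, 1],
                f_flag = flagged[, 1], f_const = rep(1, n))
  retest <- cbind(f_good = good[, 2], f_noisy = noisy[, 2],
                  f_flag = flagged[, 2], f_const = rep(1, n))
  tab <- icc_table(test, retest)
  expect_identical(tab$n, c(12L, 12L, 11L, 12L))
  expect_identical(tab$label[tab$feature == "f_good"], "repeatable")
  expect_identical(tab$label[tab$feature == "f_noisy"], "not_repeatable")
  expect_identical(tab$status[tab$feature == "f_const"],
                   "degenerate_variance")

  sm <- repeatability_summary(tab, by = rep("all", 4))
  expect_identical(sm$n_features, 3L)
  expect_identical(sm$n_excluded, 1L)
  expect_equal(sm$pct_repeatable + sm$pct_moderate + sm$pct_not_repeatable,
               100)

  rk <- rank_features(tab, n = 1)
  expect_true(rk$top$feature %in% c("f_good", "f_flag"))
  expect_identical(rk$bottom$feature, "f_noisy")
})

test_that("feature name parsing recovers variant and family", {
  f <- c("original_firstorder_Mean", "wavelet-HHH_firstorder_Skewness",
         "log-sigma-3_glszm_ZoneEntropy")
  expect_identical(petrepeat:::feature_variant(f),
                   c("original", "wavelet-HHH", "log-sigma-3"))
  expect_identical(petrepeat:::feature_family(f),
                   c("firstorder", "firstorder", "glszm"))
})
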