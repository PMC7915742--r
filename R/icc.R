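#' Two-way absolute-agreement single-measure intraclass correlation
#'
#' The ICC form for a two-way design with absolute agreement, single
#' measures (ICC(A,1) in the McGraw-Wong taxonomy):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the two-way ANOVA mean
#' squares for rows (subjects), columns (measurements) and error, `k` the
#' number of measurements per subject and `n` the number of subjects. Ranges
#' from 1 (perfect repeatability) to -1.
#'
#' @param m Numeric matrix, n subjects x k measurements (k = 2 for
#'   test/retest), no missing values.
#' @return List with `icc`, `ms_r`, `ms_c`, `ms_e`, `n`, `k`. For a matrix
#'   with zero total variance the ICC is undefined and returned as `NaN`.
#' @export
icc_a1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L) stop("ICC needs n >= 2 subjects", call. = FALSE)
  if (k < 2L) stop("ICC needs k >= 2 measurements", call. = FALSE)
  if (any(!is.finite(m))) stop("rating matrix contains non-finite values",
                               call. = FALSE)
  gm <- mean(m)
  rm_ <- rowMeans(m)
  cm <- colMeans(m)
  ss_r <- k * sum((rm_ - gm)^2)
  ss_c <- n * sum((cm - gm)^2)
  ss_t <- sum((m - gm)^2)
  ss_e <- ss_t - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  icc <- if (ss_t <= 0 || denom == 0) NaN else (ms_r - ms_e) / denom
  list(icc = icc, ms_r = ms_r, ms_c = ms_c, ms_e = ms_e, n = n, k = k)
}

#' Exact F-based confidence interval for ICC(A,1)
#'
#' The McGraw-Wong interval for the two-way absolute-agreement
#' single-measure ICC, as used by the standard reliability implementations.
#'
#' @param m Rating matrix (n x k), as for [icc_a1()].
#' @param alpha Two-sided error rate, default 0.05 (a 95% interval).
#' @return List with `icc`, `ci_low`, `ci_high`, mean squares, `n`, `k`.
#'   Degenerate inputs (zero total variance) return `NaN` bounds; a perfect
#'   agreement matrix (MSE = 0, between-subject variance > 0) returns
#'   `ci_high = 1`.
#' @export
icc_ci <- function(m, alpha = 0.05) {
  fit <- icc_a1(m)
  n <- fit$n; k <- fit$k
  ms_r <- fit$ms_r; ms_c <- fit$ms_c; ms_e <- fit$ms_e
  r <- fit$icc
  if (!is.finite(r)) {
    return(c(fit, list(ci_low = NaN, ci_high = NaN)))
  }
  if (ms_e == 0 && ms_c == 0) {
    # perfect agreement: the interval degenerates at 1
    return(c(fit, list(ci_low = if (n > 2) 1 else NaN, ci_high = 1)))
  }
  a <- (k * r) / (n * (1 - r))
  b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
  if (r >= 1) {
    return(c(fit, list(ci_low = NaN, ci_high = 1)))
  }
  v <- (a * ms_c + b * ms_e)^2 /
    ((a * ms_c)^2 / (k - 1) + (b * ms_e)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, df1 = n - 1, df2 = v)
  f_u <- stats::qf(1 - alpha / 2, df1 = v, df2 = n - 1)
  ci_low <- n * (ms_r - f_l * ms_e) /
    (f_l * (k * ms_c + (k * n - k - n) * ms_e) + n * ms_r)
  ci_high <- n * (f_u * ms_r - ms_e) /
    (k * ms_c + (k * n - k - n) * ms_e + n * f_u * ms_r)
  c(fit, list(ci_low = ci_low, ci_high = ci_high))
}

#' Classify repeatability from the ICC confidence interval
#'
#' Three-band rule on the 95% CI: `repeatable` when both limits lie in
#' \[0.91, 1.00\]; `moderate` when the upper limit lies in \[0.91, 1.00\] and
#' the lower limit in \[0.75, 1.00\]; otherwise `not_repeatable`.
#' Precedence repeatable > moderate > not_repeatable; any CI matching no
#' band (including negative lower limits and undefined CIs) is
#' `not_repeatable` — the conservative reading.
#'
#' @param ci_low,ci_high CI bounds (vectorized).
#' @return Character vector of labels.
#' @export
classify_icc <- function(ci_low, ci_high) {
  out <- rep("not_repeatable", length(ci_low))
  ok <- is.finite(ci_low) & is.finite(ci_high)
  moderate <- ok & ci_high >= 0.91 & ci_high <= 1 & ci_low >= 0.75 & ci_low <= 1
  repeatable <- ok & ci_low >= 0.91 & ci_low <= 1 & ci_high >= 0.91 & ci_high <= 1
  out[moderate] <- "moderate"
  out[repeatable] <- "repeatable"
  out
}

#' Per-feature ICC table for a cohort feature matrix pair
#'
#' Runs [icc_ci()] feature by feature on matched test/retest feature
#' matrices. Subjects with a non-finite (flagged undefined) value in either
#' condition are dropped pairwise per feature; features retaining fewer than
#' `min_n` subjects, or with degenerate variance, get `NaN` ICC and label
#' `not_repeatable` with `status` recording why.
#'
#' @param test,retest Numeric matrices, subjects x features, identical
#'   dimnames.
#' @param alpha CI error rate, default 0.05.
#' @param min_n Minimum subjects per feature for reporting, default 5.
#' @return Data frame: feature, icc, ci_low, ci_high, ms_r, ms_c, ms_e, n,
#'   label, status.
#' @export
icc_table <- function(test, retest, alpha = 0.05, min_n = 5L) {
  stopifnot(identical(dim(test), dim(retest)),
            identical(colnames(test), colnames(retest)))
  feats <- colnames(test)
  rows <- lapply(seq_along(feats), function(f) {
    x <- cbind(test[, f], retest[, f])
    keep <- is.finite(x[, 1]) & is.finite(x[, 2])
    x <- x[keep, , drop = FALSE]
    base <- data.frame(feature = feats[f], icc = NaN, ci_low = NaN,
                       ci_high = NaN, ms_r = NaN, ms_c = NaN, ms_e = NaN,
                       n = nrow(x), label = "not_repeatable",
                       status = "ok", stringsAsFactors = FALSE)
    if (nrow(x) < max(2L, min_n)) {
      base$status <- "too_few_subjects"
      return(base)
    }
    fit <- icc_ci(x, alpha = alpha)
    base$icc <- fit$icc
    base$ci_low <- fit$ci_low
    base$ci_high <- fit$ci_high
    base$ms_r <- fit$ms_r
    base$ms_c <- fit$ms_c
    base$ms_e <- fit$ms_e
    if (!is.finite(fit$icc)) {
      base$status <- "degenerate_variance"
    } else {
      base$label <- classify_icc(fit$ci_low, fit$ci_high)
    }
    base
  })
  do.call(rbind, rows)
}

feature_family <- function(feature) {
  sub("^(original|wavelet-[LH]{3}|log-sigma-[0-9.]+)_([a-z]+)_.*$", "\\2",
      feature)
}

feature_variant <- function(feature) {
  sub("^(original|wavelet-[LH]{3}|log-sigma-[0-9.]+)_.*$", "\\1", feature)
}

#' Repeatability summary by grouping
#'
#' Percentage of repeatable / moderate / not-repeatable features per group
#' (feature family, image variant, or any custom key). Features with a
#' non-`"ok"` status are excluded from the denominators, with the excluded
#' count reported.
#'
#' @param icc_tab Output of [icc_table()].
#' @param by `"family"`, `"variant"`, or a vector of group keys (one per
#'   feature row).
#' @return Data frame: group, n_features, n_excluded, pct_repeatable,
#'   pct_moderate, pct_not_repeatable.
#' @export
repeatability_summary <- function(icc_tab, by = "family") {
  key <- if (identical(by, "family")) {
    feature_family(icc_tab$feature)
  } else if (identical(by, "variant")) {
    feature_variant(icc_tab$feature)
  } else {
    stopifnot(length(by) == nrow(icc_tab))
    as.character(by)
  }
  groups <- unique(key)
  rows <- lapply(groups, function(g) {
    sub <- icc_tab[key == g, ]
    ok <- sub$status == "ok"
    n_ok <- sum(ok)
    pct <- function(lab) if (n_ok) 100 * sum(sub$label[ok] == lab) / n_ok
      else NA_real_
    data.frame(group = g, n_features = n_ok, n_excluded = sum(!ok),
               pct_repeatable = pct("repeatable"),
               pct_moderate = pct("moderate"),
               pct_not_repeatable = pct("not_repeatable"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Top and bottom features by ICC
#' @param icc_tab Output of [icc_table()].
#' @param n How many of each, default 10.
#' @return List with data frames `top` and `bottom` (status `"ok"` rows only).
#' @export
rank_features <- function(icc_tab, n = 10L) {
  ok <- icc_tab[icc_tab$status == "ok" & is.finite(icc_tab$icc), ]
  ord <- order(ok$icc, decreasing = TRUE)
  list(top = utils::head(ok[ord, ], n),
       bottom = utils::head(ok[rev(ord), ], n))
}
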