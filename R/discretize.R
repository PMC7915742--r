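#' Fixed-bin-width gray-level discretization
#'
#' Maps VOI intensities to integer gray levels with a fixed bin width
#' anchored at the VOI minimum: `level = floor((x - min) / bin_width) + 1`.
#' The recommended PET setting is a bin width of 0.15 SUV, which for a
#' typical tumor VOI yields on the order of 64 occupied bins; the realized
#' bin count is reported and a warning raised when it differs from the
#' nominal 64 (suppressible via
#' `options(petrepeat.warn_bins = FALSE)`).
#'
#' @param values Numeric vector of in-VOI intensities (>= 1 value, finite).
#' @param bin_width Positive bin width in intensity units, default 0.15.
#' @param nominal_bins Nominal bin count used for the warning, default 64.
#' @return A `discretized_voi` list: `levels` (integer vector, 1..Ng), `ng`,
#'   `bin_width`, `bin_edges`.
#' @export
discretize <- function(values, bin_width = 0.15, nominal_bins = 64L) {
  if (length(values) < 1L) stop("VOI has no voxels", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite VOI values", call. = FALSE)
  check_scalar(bin_width, "bin_width")
  lo <- min(values)
  rng <- max(values) - lo
  lev <- as.integer(floor((values - lo) / bin_width)) + 1L
  # half-open bins [lo + (k-1)w, lo + kw), except the top edge is closed:
  # a maximum falling exactly on an edge stays in the last occupied bin
  if (rng > 0) {
    nbins <- as.integer(ceiling(rng / bin_width))
    lev <- pmin(lev, nbins)
  }
  ng <- max(lev)
  if (!is.na(nominal_bins) && ng != nominal_bins &&
      isTRUE(getOption("petrepeat.warn_bins", TRUE))) {
    warning(sprintf("realized bin count %d differs from nominal %d", ng,
                    nominal_bins))
  }
  structure(list(levels = lev, ng = ng, bin_width = bin_width,
                 bin_edges = lo + bin_width * (0:ng)),
            class = "discretized_voi")
}

#' First-order (histogram) radiomics features
#'
#' The 18 intensity-statistics features. `Entropy` and `Uniformity` are
#' computed on the fixed-bin-width discretized histogram (base-2 log);
#' `Skewness` and `Kurtosis` use population moments, with `Kurtosis` not
#' excess-corrected; `Variance` is the population variance. On a
#' zero-variance VOI, `Skewness` and `Kurtosis` are undefined and returned
#' as `NaN` (flagged rather than fabricated, so they are excluded from
#' downstream repeatability scoring).
#'
#' @param values Numeric vector of in-VOI intensities.
#' @param voxel_volume_mm3 Voxel volume in mm^3 (for `TotalEnergy`).
#' @param bin_width Discretization bin width for `Entropy`/`Uniformity`.
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(values, voxel_volume_mm3 = 1,
                                 bin_width = 0.15) {
  n <- length(values)
  if (n < 1L) stop("VOI has no voxels", call. = FALSE)
  m <- mean(values)
  dev <- values - m
  m2 <- mean(dev^2)
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  p <- tabulate(discretize(values, bin_width, nominal_bins = NA)$levels)
  p <- p[p > 0] / n
  inner <- values[values >= q[1] & values <= q[5]]
  c(
    Energy = sum(values^2),
    TotalEnergy = voxel_volume_mm3 * sum(values^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(values),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(values),
    Mean = m,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(dev)),
    RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else NaN,
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (m2 > 0) mean(dev^3) / m2^1.5 else NaN,
    Kurtosis = if (m2 > 0) mean(dev^4) / m2^2 else NaN,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}
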