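#' @useDynLib petrepeat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Keeps all simulation entry points referentially
# transparent in their seed argument.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Counter-based per-subject seed derivation: changing the cohort size never
# reshuffles earlier subjects. Kept below 2^31 - 1.
derive_seed <- function(master_seed, counter) {
  as.integer((as.double(master_seed) * 48271 + counter * 9973) %% 2147483647)
}

# Sampled, normalized 1D Gaussian kernel for a sigma given in voxels.
# Truncated at 4 sigma; sums to exactly 1.
gaussian_kernel_1d <- function(sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma_vox)))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array; fwhm in mm, spacing-aware.
# mode: "reflect", "wrap", or "nearest".
gaussian_smooth_3d <- function(values, spacing, fwhm_mm, mode = "reflect") {
  if (fwhm_mm <= 0) return(values)
  mode_i <- match(match.arg(mode, c("reflect", "wrap", "nearest")),
                  c("reflect", "wrap", "nearest")) - 1L
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(values)
  out <- values
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_mm / spacing[axis])
    if (length(k) == 1L) next
    origin <- (length(k) - 1L) %/% 2L
    out <- array(cpp_conv_axis(as.numeric(out), as.integer(d), k,
                               axis - 1L, origin, mode_i), dim = d)
  }
  out
}

check_scalar <- function(x, arg, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0)) {
    stop(sprintf("`%s` must be a %sfinite scalar", arg,
                 if (positive) "positive " else ""), call. = FALSE)
  }
  invisible(x)
}
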