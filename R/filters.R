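#' Scale-normalized Laplacian-of-Gaussian filter
#'
#' Band-pass filter emphasizing blob-like structure at physical scale
#' `sigma` (mm). Computed separably: for each axis, the image is convolved
#' with the sampled second derivative of a Gaussian along that axis and with
#' the sampled Gaussian along the two others; the three responses are summed
#' and multiplied by `sigma^2` (scale normalization, so responses are
#' comparable across sigmas). Kernels are spacing-aware; boundaries use
#' reflective padding. Second-derivative kernels are mean-corrected so the
#' response to a constant image is exactly zero.
#'
#' @param image A `pet_image`.
#' @param sigma Scale in mm (> 0). A warning is raised when `sigma` is
#'   smaller than half the largest voxel edge (under-resolved kernel).
#' @return A `pet_image` on the same grid, units `"LoG"`.
#' @export
log_filter <- function(image, sigma) {
  stopifnot_pet_image(image)
  check_scalar(sigma, "sigma")
  if (sigma < max(image$spacing) / 2) {
    warning(sprintf(
      "sigma %.3g mm is under-resolved for %.3g mm voxels", sigma,
      max(image$spacing)))
  }
  d <- dim(image$values)
  out <- array(0, dim = d)
  kernels <- lapply(1:3, function(axis) {
    sp <- image$spacing[axis]
    s_vox <- sigma / sp
    r <- max(1L, as.integer(ceiling(4 * s_vox)))
    x <- seq(-r, r) * sp                       # physical mm offsets
    g <- exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
    g2 <- g * (x^2 - sigma^2) / sigma^4        # analytic d2/dx2 of Gaussian
    g <- g * sp                                # Riemann weights -> unit DC
    g <- g / sum(g)
    g2 <- g2 * sp
    g2 <- g2 - mean(g2)                        # enforce zero DC response
    list(smooth = g, deriv2 = g2)
  })
  for (axis in 1:3) {
    part <- as.numeric(image$values)
    for (ax2 in 1:3) {
      k <- if (ax2 == axis) kernels[[ax2]]$deriv2 else kernels[[ax2]]$smooth
      origin <- (length(k) - 1L) %/% 2L
      part <- cpp_conv_axis(part, as.integer(d), k, ax2 - 1L, origin, 0L)
    }
    out <- out + array(part, dim = d)
  }
  pet_image(sigma^2 * out, spacing = image$spacing, origin = image$origin,
            units = "LoG")
}

# Coiflet-1 decomposition filters. The low-pass taps satisfy
# sum = sqrt(2) (DC gain) and orthonormality of even shifts; the high-pass
# filter is the quadrature mirror of the low-pass.
coif1_filters <- function() {
  lo <- c(-0.015655728135464787, -0.07273261951252645,
          0.3848648468648578, 0.8525720202116004,
          0.33789766245748187, -0.07273261951252645)
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  list(lo = lo, hi = hi)
}

#' Single-level undecimated 3D wavelet decomposition
#'
#' Applies the separable stationary (undecimated) wavelet transform with all
#' eight combinations of low- (L) and high-pass (H) filtering along the
#' three axes, yielding the variants HHH, HHL, ..., LLL on the source grid
#' (so VOI masks remain valid). Default kernel: Coiflet-1; boundary
#' handling: periodic, the convention of stationary transforms.
#'
#' @param image A `pet_image`.
#' @param kernel Currently `"coif1"`.
#' @return Named list of eight `pet_image`s, names `"LLL"`, `"LLH"`, `"LHL"`,
#'   `"LHH"`, `"HLL"`, `"HLH"`, `"HHL"`, `"HHH"` (letter order = axis order
#'   x, y, z).
#' @export
wavelet_decompositions <- function(image, kernel = "coif1") {
  stopifnot_pet_image(image)
  kernel <- match.arg(kernel, "coif1")
  f <- coif1_filters()
  d <- dim(image$values)
  if (any(d < length(f$lo))) {
    stop("grid too small for one wavelet decomposition level", call. = FALSE)
  }
  combos <- expand.grid(x = c("L", "H"), y = c("L", "H"), z = c("L", "H"),
                        stringsAsFactors = FALSE)
  out <- vector("list", 8L)
  nm <- character(8L)
  origin <- (length(f$lo) - 1L) %/% 2L
  for (i in seq_len(8L)) {
    vals <- as.numeric(image$values)
    for (axis in 1:3) {
      k <- if (combos[i, axis] == "L") f$lo else f$hi
      vals <- cpp_conv_axis(vals, as.integer(d), k, axis - 1L, origin, 1L)
    }
    nm[i] <- paste0(combos[i, 1], combos[i, 2], combos[i, 3])
    out[[i]] <- pet_image(array(vals, dim = d), spacing = image$spacing,
                          origin = image$origin,
                          units = paste0("wavelet-", nm[i]))
  }
  names(out) <- nm
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

#' All 14 image variants for the feature bank
#'
#' The feature bank is recomputed on 14 variants of each image: the original,
#' the 8 single-level wavelet decompositions, and 5 Laplacian-of-Gaussian
#' scales (sigma 1-5 mm). 14 variants x 93 features = 1,302 features.
#'
#' @param image A `pet_image`.
#' @param log_sigmas LoG scales in mm, default `1:5`.
#' @param wavelet_kernel Passed to [wavelet_decompositions()].
#' @return Named list of 14 `pet_image`s; names `"original"`,
#'   `"wavelet-LLL"` ... `"wavelet-HHH"`, `"log-sigma-1"` ... `"log-sigma-5"`.
#' @export
image_variants <- function(image, log_sigmas = 1:5, wavelet_kernel = "coif1") {
  stopifnot_pet_image(image)
  wav <- wavelet_decompositions(image, kernel = wavelet_kernel)
  names(wav) <- paste0("wavelet-", names(wav))
  logs <- lapply(log_sigmas, function(s) log_filter(image, s))
  names(logs) <- sprintf("log-sigma-%g", log_sigmas)
  c(list(original = image), wav, logs)
}
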