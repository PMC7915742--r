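#' Phantom specification for a synthetic glioma FET PET subject
#'
#' Describes a brain-like volume of uniform amino-acid tracer uptake
#' containing a spherical tumor with a tumor-to-brain contrast above the
#' clinical segmentation threshold and a smooth multiplicative intratumoral
#' texture field. Defaults emulate a static 20-40 min FET uptake image:
#' background SUV 1.0, tumor-to-brain ratio 2.0 (above the 1.6 threshold),
#' 4 mm point-spread blur typical of a high-resolution brain PET system.
#'
#' @param shape Integer length-3 grid shape (voxels). Default `c(96, 96, 96)`.
#' @param spacing Voxel spacing in mm. Default 2 mm isotropic.
#' @param background_uptake Background SUV. Default 1.0.
#' @param tumor_center Tumor center in mm (physical coordinates). Default at
#'   +24 mm lateral offset from the grid center, emulating a hemispheric lesion.
#' @param tumor_radius Tumor radius in mm. Default 15 (volume 14.1 mL).
#' @param tbr_contrast Tumor mean / background mean. Must exceed 1 and, for a
#'   segmentable lesion, the 1.6 tumor-to-brain threshold. Default 2.0.
#' @param texture_scale Correlation length of the intratumoral texture field
#'   in mm. Default 6.
#' @param texture_amplitude Fractional amplitude of the multiplicative texture
#'   (standard deviation of the modulation), in `[0, 1)`. Default 0.2.
#' @param psf_fwhm Gaussian point-spread FWHM in mm. Default 4.
#' @param exposure Expected counts per unit activity per voxel; scales
#'   activity into detected events. Default 400.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96, 96, 96),
                         spacing = c(2, 2, 2),
                         background_uptake = 1.0,
                         tumor_center = NULL,
                         tumor_radius = 15,
                         tbr_contrast = 2.0,
                         texture_scale = 6,
                         texture_amplitude = 0.2,
                         psf_fwhm = 4,
                         exposure = 400) {
  shape <- as.integer(shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(tumor_center)) {
    center_mm <- (shape - 1) * spacing / 2
    tumor_center <- center_mm + c(0.25 * shape[1] * spacing[1], 0, 0)
  }
  check_scalar(background_uptake, "background_uptake")
  check_scalar(tumor_radius, "tumor_radius")
  check_scalar(tbr_contrast, "tbr_contrast")
  check_scalar(exposure, "exposure")
  if (tbr_contrast <= 1) {
    stop("`tbr_contrast` must be > 1 for a detectable tumor", call. = FALSE)
  }
  if (texture_amplitude < 0 || texture_amplitude >= 1) {
    stop("`texture_amplitude` must be in [0, 1)", call. = FALSE)
  }
  if (psf_fwhm < 0) stop("`psf_fwhm` must be >= 0", call. = FALSE)
  spec <- list(shape = shape, spacing = as.numeric(spacing),
               background_uptake = background_uptake,
               tumor_center = as.numeric(tumor_center),
               tumor_radius = tumor_radius, tbr_contrast = tbr_contrast,
               texture_scale = texture_scale,
               texture_amplitude = texture_amplitude,
               psf_fwhm = psf_fwhm, exposure = exposure)
  class(spec) <- "phantom_spec"
  spec
}

# Logical sphere on the voxel grid of `spec`-like geometry:
# voxel included iff its center lies within `radius` of `center_mm`.
sphere_indicator <- function(shape, spacing, origin, center_mm, radius) {
  cx <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  dx2 <- (cx - center_mm[1])^2
  dy2 <- (cy - center_mm[2])^2
  dz2 <- (cz - center_mm[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  d2 <= radius^2
}

#' Generate a synthetic activity map (brain + tumor phantom)
#'
#' Builds a piecewise map (uniform background, spherical tumor at the stated
#' tumor-to-brain contrast), modulates the tumor by a smooth multiplicative
#' Gaussian random field of the stated amplitude and correlation length, then
#' applies the point-spread blur.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed controlling the texture field.
#' @return A `pet_image` with units `"activity"` (SUV-scaled activity).
#' @export
make_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  origin <- c(0, 0, 0)
  extent <- (spec$shape - 1) * spec$spacing
  if (any(spec$tumor_center - spec$tumor_radius < 0) ||
      any(spec$tumor_center + spec$tumor_radius > extent)) {
    stop("tumor sphere does not fit inside the grid", call. = FALSE)
  }
  tumor <- sphere_indicator(spec$shape, spec$spacing, origin,
                            spec$tumor_center, spec$tumor_radius)
  vals <- array(spec$background_uptake, dim = spec$shape)
  tumor_uptake <- spec$tbr_contrast * spec$background_uptake
  if (spec$texture_amplitude > 0) {
    field <- with_seed(seed, {
      w <- array(stats::rnorm(prod(spec$shape)), dim = spec$shape)
      gaussian_smooth_3d(w, spec$spacing,
                         fwhm_mm = 2 * sqrt(2 * log(2)) * spec$texture_scale,
                         mode = "wrap")
    })
    field <- field / stats::sd(field)          # unit-variance smooth field
    mod <- 1 + spec$texture_amplitude * field
    vals[tumor] <- tumor_uptake * mod[tumor]
  } else {
    vals[tumor] <- tumor_uptake
  }
  if (any(vals < 0)) {
    warning("negative uptake after texture modulation clipped to 0")
    vals[vals < 0] <- 0
  }
  if (spec$psf_fwhm > 0) {
    vals <- gaussian_smooth_3d(vals, spec$spacing, spec$psf_fwhm,
                               mode = "nearest")
  }
  img <- pet_image(vals, spacing = spec$spacing, origin = origin,
                   units = "activity")
  attr(img, "true_tumor_mask") <- tumor
  attr(img, "tumor_center") <- spec$tumor_center
  img
}

#' Simulate a Poisson counts image from an activity map
#'
#' Each voxel's detected events are drawn independently from
#' `Poisson(exposure * activity)`, emulating the statistical image noise of
#' radioactive decay.
#'
#' @param map A `pet_image` activity map (non-negative, finite).
#' @param exposure Positive scalar scaling activity to expected counts.
#' @param seed Integer seed.
#' @return A `pet_image` with integer-valued counts and units `"counts"`;
#'   the exposure is attached as attribute `"exposure"`.
#' @export
simulate_counts <- function(map, exposure, seed = 1L) {
  stopifnot_pet_image(map)
  check_scalar(exposure, "exposure")
  if (any(!is.finite(map$values))) {
    stop("activity map contains non-finite values", call. = FALSE)
  }
  lambda <- exposure * pmax(map$values, 0)
  counts <- with_seed(seed, stats::rpois(length(lambda), lambda))
  img <- pet_image(array(as.numeric(counts), dim = dim(map$values)),
                   spacing = map$spacing, origin = map$origin,
                   units = "counts")
  attr(img, "exposure") <- exposure
  img
}

#' Split a counts image into two independent halves
#'
#' Emulates the dual reconstruction in which events with odd time stamps form
#' the test image and events with even time stamps the retest image. Each of
#' the N events in a voxel is assigned to half A with probability 1/2
#' (binomial thinning), which for Poisson counts yields two exactly
#' independent Poisson halves with half the original mean. The halves always
#' sum voxelwise to the input. A deterministic alternating split
#' (`method = "alternate"`: ceiling(N/2) vs floor(N/2)) is available for
#' sensitivity analysis; it conserves counts but its halves are not
#' independent.
#'
#' @param counts A counts `pet_image` (non-negative integers).
#' @param seed Integer seed (ignored for `method = "alternate"`).
#' @param method `"thinning"` (default) or `"alternate"`.
#' @return List with elements `a` and `b`, both counts `pet_image`s.
#' @export
split_events <- function(counts, seed = 1L, method = c("thinning", "alternate")) {
  stopifnot_pet_image(counts)
  method <- match.arg(method)
  n <- counts$values
  if (any(n < 0) || any(n != round(n))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  a <- if (method == "thinning") {
    with_seed(seed, stats::rbinom(length(n), size = as.integer(n), prob = 0.5))
  } else {
    ceiling(n / 2)
  }
  half <- function(v) {
    img <- pet_image(array(as.numeric(v), dim = dim(n)),
                     spacing = counts$spacing, origin = counts$origin,
                     units = "counts")
    attr(img, "exposure") <- attr(counts, "exposure") / 2
    img
  }
  list(a = half(a), b = half(n - a))
}

#' Reconstruct an image from counts
#'
#' Desk-scale stand-in for iterative tomographic reconstruction:
#' `image = counts / exposure` followed by optional Gaussian post-smoothing.
#' Unbiased for the underlying activity map.
#'
#' @param counts A counts `pet_image`.
#' @param exposure Positive scalar; the exposure the counts were generated
#'   with (halved automatically for split halves if taken from the
#'   `"exposure"` attribute).
#' @param post_smoothing_fwhm Gaussian FWHM in mm, 0 for none.
#' @return A `pet_image` in activity units.
#' @export
reconstruct_image <- function(counts, exposure = attr(counts, "exposure"),
                              post_smoothing_fwhm = 0) {
  stopifnot_pet_image(counts)
  check_scalar(exposure, "exposure")
  vals <- counts$values / exposure
  if (post_smoothing_fwhm > 0) {
    vals <- gaussian_smooth_3d(vals, counts$spacing, post_smoothing_fwhm,
                               mode = "nearest")
  }
  pet_image(vals, spacing = counts$spacing, origin = counts$origin,
            units = "activity")
}

#' Cohort specification for a two-genotype synthetic population
#'
#' Emulates a glioma cohort with two genotype groups (IDH-wildtype and
#' IDH-mutant) differing in tumor volume and intratumoral texture. Defaults
#' mirror the clinical cohort structure used throughout: 30 wildtype and 20
#' mutant subjects, group mean tumor volumes 21.4 vs 16.7 mL, and slightly
#' stronger heterogeneity and uptake contrast in the wildtype group.
#' Tumor volumes are drawn lognormally (volumes are strictly positive and
#' right-skewed in glioma cohorts).
#'
#' @param n_per_group Named integer vector of subjects per genotype
#'   (each >= 2; the intraclass correlation is undefined below n = 2).
#' @param volume_mean_ml Named numeric, group mean tumor volume (mL).
#' @param volume_cv Lognormal coefficient of variation of volumes. Default 0.6.
#' @param tbr_contrast Named numeric, group tumor-to-brain contrast.
#' @param texture_amplitude Named numeric, group texture amplitude.
#' @param texture_scale Texture correlation length mm (shared). Default 6.
#' @param shape,spacing,psf_fwhm,exposure,background_uptake Grid and imaging
#'   parameters shared by all subjects (see [phantom_spec()]).
#' @param seed Master seed; per-subject seeds are derived by a counter scheme
#'   so extending the cohort never reshuffles earlier subjects.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(wildtype = 30L, mutant = 20L),
                        volume_mean_ml = c(wildtype = 21.4, mutant = 16.7),
                        volume_cv = 0.6,
                        tbr_contrast = c(wildtype = 2.5, mutant = 2.0),
                        texture_amplitude = c(wildtype = 0.30, mutant = 0.15),
                        texture_scale = 6,
                        shape = c(96, 96, 96), spacing = c(2, 2, 2),
                        psf_fwhm = 4, exposure = 400,
                        background_uptake = 1.0,
                        seed = 1L) {
  groups <- names(n_per_group)
  if (is.null(groups) || any(!nzchar(groups))) {
    stop("`n_per_group` must be a named vector of genotype labels",
         call. = FALSE)
  }
  if (any(n_per_group < 2L)) {
    stop("each genotype group needs n >= 2 subjects (ICC undefined below 2)",
         call. = FALSE)
  }
  for (nm in c("volume_mean_ml", "tbr_contrast", "texture_amplitude")) {
    v <- get(nm)
    if (!all(groups %in% names(v))) {
      stop(sprintf("`%s` must be named for every genotype group", nm),
           call. = FALSE)
    }
  }
  if (any(volume_mean_ml <= 0)) stop("volumes must be > 0", call. = FALSE)
  structure(list(
    n_per_group = n_per_group, volume_mean_ml = volume_mean_ml,
    volume_cv = volume_cv, tbr_contrast = tbr_contrast,
    texture_amplitude = texture_amplitude, texture_scale = texture_scale,
    shape = as.integer(shape),
    spacing = if (length(spacing) == 1L) rep(spacing, 3) else as.numeric(spacing),
    psf_fwhm = psf_fwhm, exposure = exposure,
    background_uptake = background_uptake, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Simulate a test/retest cohort
#'
#' For each subject: draw tumor volume from the group's lognormal
#' distribution, build the phantom, simulate Poisson counts, split the events
#' into two independent halves and reconstruct both. Fully deterministic
#' given the master seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of subject records, each with elements `pair` (a
#'   [trt_pair()]), `genotype`, `true_volume_ml`, `tumor_center` (mm) and
#'   `subject_id`; the cohort manifest data frame is attached as attribute
#'   `"manifest"`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- list()
  manifest <- NULL
  counter <- 0L
  for (g in names(spec$n_per_group)) {
    mu <- spec$volume_mean_ml[[g]]
    cv <- spec$volume_cv
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(mu) - sdlog^2 / 2
    for (i in seq_len(spec$n_per_group[[g]])) {
      counter <- counter + 1L
      sid <- sprintf("S%03d", counter)
      s_vol   <- derive_seed(spec$seed, counter * 4L)
      s_tex   <- derive_seed(spec$seed, counter * 4L + 1L)
      s_cnt   <- derive_seed(spec$seed, counter * 4L + 2L)
      s_split <- derive_seed(spec$seed, counter * 4L + 3L)
      vol_ml <- with_seed(s_vol, stats::rlnorm(1, meanlog, sdlog))
      radius <- (3 * vol_ml * 1000 / (4 * pi))^(1 / 3)
      # keep the tumor (and the surrounding sphere-VOI series) inside the grid
      max_r <- min((spec$shape - 1) * spec$spacing) / 2 - 2 * max(spec$spacing)
      radius <- min(radius, max_r / 2)
      ps <- phantom_spec(
        shape = spec$shape, spacing = spec$spacing,
        background_uptake = spec$background_uptake,
        tumor_radius = radius,
        tbr_contrast = spec$tbr_contrast[[g]],
        texture_scale = spec$texture_scale,
        texture_amplitude = spec$texture_amplitude[[g]],
        psf_fwhm = spec$psf_fwhm, exposure = spec$exposure
      )
      phantom <- make_phantom(ps, seed = s_tex)
      counts <- simulate_counts(phantom, exposure = spec$exposure, seed = s_cnt)
      halves <- split_events(counts, seed = s_split)
      test <- reconstruct_image(halves$a, exposure = spec$exposure / 2)
      retest <- reconstruct_image(halves$b, exposure = spec$exposure / 2)
      subjects[[counter]] <- list(
        pair = trt_pair(test, retest, sid),
        genotype = g,
        true_volume_ml = 4 / 3 * pi * radius^3 / 1000,
        tumor_center = ps$tumor_center,
        subject_id = sid
      )
      manifest <- rbind(manifest, data.frame(
        subject_id = sid, genotype = g,
        true_volume_mL = 4 / 3 * pi * radius^3 / 1000,
        stringsAsFactors = FALSE
      ))
    }
  }
  attr(subjects, "manifest") <- manifest
  subjects
}
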