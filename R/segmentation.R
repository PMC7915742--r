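#' SUV calibration
#'
#' Standardized-uptake-value normalization divides tissue activity by the
#' injected activity per kilogram of body weight (typical FET protocol:
#' 3 MBq/kg).
#'
#' @param injected_dose Injected activity in MBq (> 0).
#' @param body_weight Body weight in kg (> 0).
#' @return A `suv_calibration` list.
#' @export
suv_calibration <- function(injected_dose, body_weight) {
  check_scalar(injected_dose, "injected_dose")
  check_scalar(body_weight, "body_weight")
  structure(list(injected_dose = injected_dose, body_weight = body_weight),
            class = "suv_calibration")
}

#' Convert an activity image to SUV
#'
#' `suv = activity / (injected_dose / body_weight)`. Linear in the input.
#'
#' @param image Activity-valued `pet_image`.
#' @param cal A [suv_calibration()].
#' @return A `pet_image` with units `"SUV"`.
#' @export
to_suv <- function(image, cal) {
  stopifnot_pet_image(image)
  stopifnot(inherits(cal, "suv_calibration"))
  factor <- cal$injected_dose / cal$body_weight
  pet_image(image$values / factor, spacing = image$spacing,
            origin = image$origin, units = "SUV")
}

#' Spherical VOI mask
#'
#' A voxel belongs to the sphere iff its center lies within `diameter / 2` of
#' `center` (voxel-center inclusion; no partial volumes). The realized volume
#' (`n_voxels * voxel_volume`) converges to the analytic 4/3*pi*r^3 as
#' spacing shrinks.
#'
#' @param image `pet_image` supplying the voxel grid.
#' @param center Sphere center, physical mm coordinates (length 3).
#' @param diameter Sphere diameter in mm.
#' @param label Mask label, default `"tumor_sphere"`.
#' @return A `voi_mask`; realized and analytic volumes (mL) are attached as
#'   attributes `"realized_volume_ml"` and `"analytic_volume_ml"`.
#' @export
sphere_mask <- function(image, center, diameter, label = "tumor_sphere") {
  stopifnot_pet_image(image)
  check_scalar(diameter, "diameter")
  center <- as.numeric(center)
  extent_lo <- image$origin
  extent_hi <- image$origin + (dim(image$values) - 1) * image$spacing
  if (any(center < extent_lo - diameter / 2) ||
      any(center > extent_hi + diameter / 2)) {
    stop("sphere lies fully outside the image grid", call. = FALSE)
  }
  ind <- sphere_indicator(dim(image$values), image$spacing, image$origin,
                          center, diameter / 2)
  if (!any(ind)) {
    stop("sphere contains no voxel centers (diameter below grid resolution?)",
         call. = FALSE)
  }
  m <- voi_mask(ind, label = label, nominal_diameter = diameter)
  attr(m, "realized_volume_ml") <- sum(ind) * voxel_volume(image) / 1000
  attr(m, "analytic_volume_ml") <- 4 / 3 * pi * (diameter / 2)^3 / 1000
  m
}

#' Tumor auto-contour by tumor-to-brain-ratio threshold
#'
#' Clinical-style 3D auto-contouring: compute the mean SUV in the healthy
#' background sphere, threshold the image at `threshold` times that mean
#' (default 1.6, the biopsy-validated tumor cutoff for FET), and keep the
#' 26-connected component containing the global maximum SUV voxel. The
#' result is scale-invariant: multiplying the image by any positive constant
#' leaves the contour unchanged.
#'
#' @param image SUV-valued `pet_image`.
#' @param background A `voi_mask` over normal-appearing brain.
#' @param threshold Tumor-to-brain ratio cutoff, default 1.6.
#' @return A `voi_mask` with label `"tumor_contour"`.
#' @export
auto_contour_tbr <- function(image, background, threshold = 1.6) {
  stopifnot_pet_image(image)
  stopifnot(inherits(background, "voi_mask"))
  if (!identical(dim(background$mask), dim(image$values))) {
    stop("background mask grid does not match image grid", call. = FALSE)
  }
  bg_mean <- mean(image$values[background$mask])
  if (!is.finite(bg_mean) || bg_mean <= 0) {
    stop("background mean is not positive; cannot form a ratio threshold",
         call. = FALSE)
  }
  cand <- image$values >= threshold * bg_mean
  if (!any(cand)) {
    stop("no tumor detected: no voxel reaches the ratio threshold",
         call. = FALSE)
  }
  imax <- which.max(image$values)
  if (background$mask[imax]) {
    warning("global maximum lies inside the background mask")
  }
  d <- dim(image$values)
  labels <- cpp_label_components(as.integer(cand), as.integer(d), 26L)
  labels <- array(labels, dim = d)
  keep <- labels == labels[imax] & cand
  voi_mask(keep, label = "tumor_contour")
}

#' Series of spherical tumor VOIs centered on the uptake maximum
#'
#' Places one sphere per requested diameter, all centered on the voxel of
#' maximum SUV inside the tumor mask (ties broken deterministically at the
#' lowest linear index, with a warning). Used to probe how feature
#' repeatability depends on VOI volume: the default series spans 10-40 mm
#' diameter, i.e. roughly 0.5-33.5 mL.
#'
#' @param image SUV-valued `pet_image`.
#' @param tumor Tumor `voi_mask`.
#' @param diameters Numeric vector of diameters in mm. Default
#'   `c(10, 16, 20, 24, 30, 35, 40)`.
#' @return Named list of `voi_mask`s (names `"d10"`, `"d16"`, ...), each
#'   carrying the shared `"center_mm"` attribute.
#' @export
tumor_sphere_series <- function(image, tumor,
                                diameters = c(10, 16, 20, 24, 30, 35, 40)) {
  stopifnot_pet_image(image)
  stopifnot(inherits(tumor, "voi_mask"))
  vals <- image$values
  vals[!tumor$mask] <- -Inf
  mx <- max(vals)
  hits <- which(vals == mx)
  if (length(hits) > 1L) {
    warning(sprintf("%d voxels tie at the maximum; using lowest linear index",
                    length(hits)))
  }
  imax <- hits[1L]
  ijk <- arrayInd(imax, dim(image$values))[1, ]
  center <- image$origin + (ijk - 1) * image$spacing
  out <- lapply(diameters, function(d) {
    m <- sphere_mask(image, center, d, label = "tumor_sphere")
    attr(m, "center_mm") <- center
    m
  })
  names(out) <- sprintf("d%g", diameters)
  out
}

#' Background sphere mirrored across the midline
#'
#' Convenience placement for simulation: reflects the tumor center across the
#' sagittal midplane of the grid (first axis), emulating the manual placement
#' of a background sphere in contralateral normal-appearing brain.
#'
#' @param image `pet_image` supplying the grid.
#' @param tumor_center Tumor center in mm.
#' @param diameter Sphere diameter in mm, default 30 (volume 14.1 mL).
#' @return A `voi_mask` with label `"background_sphere"`.
#' @export
background_sphere <- function(image, tumor_center, diameter = 30) {
  stopifnot_pet_image(image)
  mid <- image$origin[1] + (dim(image$values)[1] - 1) * image$spacing[1] / 2
  center <- as.numeric(tumor_center)
  center[1] <- 2 * mid - center[1]
  sphere_mask(image, center, diameter, label = "background_sphere")
}
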