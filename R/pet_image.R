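#' 3D PET image container
#'
#' A `pet_image` is a 3D numeric array with physical voxel geometry attached:
#' isotropic or anisotropic voxel spacing in mm and the physical coordinate of
#' the center of voxel (1,1,1). It is the common substrate for activity maps,
#' count images and reconstructed SUV images.
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin Numeric length-3, physical mm coordinates of the first voxel
#'   center. Defaults to `c(0, 0, 0)`.
#' @param units Character unit tag, e.g. `"activity"`, `"counts"`, `"SUV"`.
#' @return An object of class `pet_image`.
#' @export
pet_image <- function(values, spacing, origin = c(0, 0, 0),
                      units = "activity") {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, origin = origin, units = units),
    class = "pet_image"
  )
}

#' @export
print.pet_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<pet_image> %d x %d x %d voxels, spacing %s mm, units: %s\n",
    d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "), x$units
  ))
  rng <- range(x$values)
  cat(sprintf("  value range: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.pet_image <- function(x) dim(x$values)

is_pet_image <- function(x) inherits(x, "pet_image")

stopifnot_pet_image <- function(x, arg = deparse(substitute(x))) {
  if (!is_pet_image(x)) stop(sprintf("`%s` must be a pet_image", arg),
                             call. = FALSE)
  invisible(x)
}

#' Voxel volume of a pet_image in mm^3
#' @param image A `pet_image`.
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(image) {
  stopifnot_pet_image(image)
  prod(image$spacing)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# Physical mm coordinates of every voxel center along one axis.
axis_coords <- function(image, axis) {
  n <- dim(image$values)[axis]
  image$origin[axis] + (seq_len(n) - 1) * image$spacing[axis]
}

#' Test/retest image pair
#'
#' Bundles two statistically independent reconstructions of the same subject
#' on one voxel grid — the unit of repeatability analysis.
#'
#' @param test,retest `pet_image` objects on identical grids.
#' @param subject_id Character scalar.
#' @return An object of class `trt_pair`.
#' @export
trt_pair <- function(test, retest, subject_id) {
  stopifnot_pet_image(test)
  stopifnot_pet_image(retest)
  if (!same_grid(test, retest)) {
    stop("test and retest images must share grid shape, spacing and origin",
         call. = FALSE)
  }
  structure(list(test = test, retest = retest,
                 subject_id = as.character(subject_id)),
            class = "trt_pair")
}

#' @export
print.trt_pair <- function(x, ...) {
  cat(sprintf("<trt_pair> subject %s\n", x$subject_id))
  print(x$test)
  invisible(x)
}

#' Binary volume-of-interest mask
#'
#' @param mask 3D logical array, aligned voxel-for-voxel with its image.
#' @param label One of `"tumor_contour"`, `"background_sphere"`,
#'   `"tumor_sphere"`.
#' @param nominal_diameter Sphere diameter in mm (spheres only), or `NA`.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, label,
                     nominal_diameter = NA_real_) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L || !is.logical(mask)) {
    stop("`mask` must be a 3D logical array", call. = FALSE)
  }
  if (!any(mask)) stop("VOI mask is empty", call. = FALSE)
  label <- match.arg(label,
                     c("tumor_contour", "background_sphere", "tumor_sphere"))
  structure(list(mask = mask, label = label,
                 nominal_diameter = nominal_diameter),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s: %d voxels%s\n", x$label, sum(x$mask),
              if (is.na(x$nominal_diameter)) "" else
                sprintf(", nominal diameter %g mm", x$nominal_diameter)))
  invisible(x)
}

#' Realized VOI volume in mL
#' @param voi A `voi_mask`.
#' @param image The `pet_image` the mask is aligned to (provides spacing).
#' @return Volume in mL (1 mL = 1000 mm^3).
#' @export
voi_volume_ml <- function(voi, image) {
  stopifnot_pet_image(image)
  sum(voi$mask) * voxel_volume(image) / 1000
}
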