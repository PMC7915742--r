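#' Write a pet_image as a NIfTI-1 volume
#'
#' Minimal single-file NIfTI-1 (.nii / .nii.gz) writer: float64 data, voxel
#' spacing in `pixdim`, origin carried by an axis-aligned sform. This is a
#' deliberately small I/O layer for interoperability (readable by nibabel,
#' FSL, ITK); it does not attempt full NIfTI generality (no obliques, no
#' slope/intercept scaling, no extensions).
#'
#' @param image A `pet_image`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(image, path) {
  stopifnot_pet_image(image)
  d <- dim(image$values)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)

  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(36), con)                              # unused historical
  writeBin(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), con, size = 2)  # dim[8]
  writeBin(raw(14), con)                              # intent_p1..3, intent_code
  writeBin(c(64L, 64L), con, size = 2)                # datatype float64, bitpix
  writeBin(0L, con, size = 2)                         # slice_start
  writeBin(as.numeric(c(1, image$spacing, 0, 0, 0, 0)), con, size = 4) # pixdim
  writeBin(352, con, size = 4)                        # vox_offset
  writeBin(c(1, 0), con, size = 4)                    # scl_slope, scl_inter
  writeBin(0L, con, size = 2)                         # slice_end
  writeBin(raw(2), con)                               # slice_code, xyzt_units
  writeBin(c(0, 0, 0), con, size = 4)                 # cal_max, cal_min, slice_duration
  writeBin(0, con, size = 4)                          # toffset
  writeBin(raw(8), con)                               # glmax, glmin
  desc <- charToRaw(sprintf("%-80s", "petrepeat"))[1:80]
  writeBin(desc, con)                                 # descrip
  writeBin(raw(24), con)                              # aux_file
  writeBin(c(0L, 1L), con, size = 2)                  # qform_code, sform_code
  writeBin(numeric(6), con, size = 4)                 # quatern b/c/d, qoffset x/y/z
  srow <- rbind(c(image$spacing[1], 0, 0, image$origin[1]),
                c(0, image$spacing[2], 0, image$origin[2]),
                c(0, 0, image$spacing[3], image$origin[3]))
  writeBin(as.numeric(t(srow)), con, size = 4)        # srow_x/y/z
  writeBin(charToRaw(sprintf("%-16s", image$units))[1:16], con) # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)       # magic
  writeBin(raw(4), con)                               # extension flag
  writeBin(as.numeric(image$values), con, size = 8)
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' Supports little-endian single-file NIfTI-1 with datatype uint8 (2),
#' int16 (4), int32 (8), float32 (16) or float64 (64) and 3D dims.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param units Unit tag to attach (NIfTI has no canonical activity unit
#'   field); defaults to the stored intent_name if present.
#' @return A `pet_image`.
#' @export
read_nifti <- function(path, units = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 352)
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4)
  if (sizeof_hdr != 348L) stop("not a little-endian NIfTI-1 file",
                               call. = FALSE)
  dims <- readBin(hdr[41:56], "integer", n = 8, size = 2)
  if (dims[1] < 3L) stop("expected a 3D volume", call. = FALSE)
  d <- dims[2:4]
  datatype <- readBin(hdr[71:72], "integer", size = 2)
  pixdim <- readBin(hdr[77:108], "numeric", n = 8, size = 4)
  vox_offset <- readBin(hdr[109:112], "numeric", size = 4)
  sform_code <- readBin(hdr[255:256], "integer", size = 2)
  srow <- matrix(readBin(hdr[281:328], "numeric", n = 12, size = 4),
                 nrow = 3, byrow = TRUE)
  intent_raw <- hdr[329:344]
  z <- which(intent_raw == as.raw(0))
  if (length(z)) intent_raw <- intent_raw[seq_len(z[1] - 1L)]
  intent_name <- trimws(rawToChar(intent_raw))

  n <- prod(d)
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n = n, size = 2)),
    "8"  = as.numeric(readBin(con, "integer", n = n, size = 4)),
    "16" = readBin(con, "numeric", n = n, size = 4),
    "64" = readBin(con, "numeric", n = n, size = 8),
    stop(sprintf("unsupported NIfTI datatype %d", datatype), call. = FALSE)
  )
  origin <- if (sform_code > 0L) srow[, 4] else c(0, 0, 0)
  if (is.null(units)) units <- if (nzchar(intent_name)) intent_name else "unknown"
  pet_image(array(vals, dim = d), spacing = pixdim[2:4], origin = origin,
            units = units)
}

#' Write a VOI mask as a NIfTI-1 label volume
#' @param voi A `voi_mask`.
#' @param image The aligned `pet_image` (supplies geometry).
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_mask <- function(voi, image, path) {
  lab <- pet_image(array(as.numeric(voi$mask), dim = dim(voi$mask)),
                   spacing = image$spacing, origin = image$origin,
                   units = voi$label)
  write_nifti(lab, path)
}
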