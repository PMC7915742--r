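FEATURE_FAMILIES <- c(firstorder = 18L, glcm = 24L, gldm = 14L,
                      glrlm = 16L, glszm = 16L, ngtdm = 5L)

VARIANT_NAMES <- c("original",
                   paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH",
                                        "HLL", "HLH", "HHL", "HHH")),
                   sprintf("log-sigma-%d", 1:5))

# Crop the mask's bounding box (plus nothing: matrices only look at distance-1
# neighbors, which cannot cross the mask boundary) and return the discretized
# integer level array, 0 outside the mask.
levels_array <- function(image, voi, bin_width) {
  idx <- which(voi$mask, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  sub <- image$values[rng[1, 1]:rng[2, 1],
                      rng[1, 2]:rng[2, 2],
                      rng[1, 3]:rng[2, 3], drop = FALSE]
  msub <- voi$mask[rng[1, 1]:rng[2, 1],
                   rng[1, 2]:rng[2, 2],
                   rng[1, 3]:rng[2, 3], drop = FALSE]
  disc <- discretize(sub[msub], bin_width, nominal_bins = NA)
  lev <- array(0L, dim = dim(sub))
  lev[msub] <- disc$levels
  list(levels = lev, ng = disc$ng)
}

#' The 93-feature radiomics set for one image and one VOI
#'
#' 18 first-order features plus 75 texture features (24 GLCM + 14 GLDM +
#' 16 GLRLM + 16 GLSZM + 5 NGTDM) computed on the native grid (no
#' resampling). Intensities are discretized inside the VOI with a fixed bin
#' width anchored at the VOI minimum. Features whose formula is undefined on
#' the input (e.g. single-voxel VOI for pair-based families, zero-variance
#' skewness) are returned as `NaN` rather than a fabricated constant.
#'
#' @param image A `pet_image` (any variant).
#' @param voi A `voi_mask` on the same grid.
#' @param bin_width Discretization bin width, default 0.15.
#' @return Named numeric vector of 93 features, names `<family>_<Feature>`.
#' @export
extract_features <- function(image, voi, bin_width = 0.15) {
  stopifnot_pet_image(image)
  if (!identical(dim(voi$mask), dim(image$values))) {
    stop("VOI mask grid does not match image grid", call. = FALSE)
  }
  vals <- image$values[voi$mask]
  fo <- first_order_features(vals, voxel_volume_mm3 = voxel_volume(image),
                             bin_width = bin_width)
  la <- levels_array(image, voi, bin_width)
  tm <- texture_matrices(la$levels, la$ng)
  fam <- list(
    firstorder = fo,
    glcm = glcm_features(tm$glcm),
    gldm = gldm_features(tm$gldm),
    glrlm = glrlm_features(tm$glrlm, tm$n_voxels),
    glszm = glszm_features(tm$glszm, tm$n_voxels),
    ngtdm = ngtdm_features(tm$ngtdm)
  )
  unlist(lapply(names(fam), function(f) {
    stats::setNames(fam[[f]], paste0(f, "_", names(fam[[f]])))
  }))
}

#' Full 1,302-feature vector over the 14 image variants
#'
#' Computes the 93-feature set on the original image and on its 13 filtered
#' variants (8 wavelet decompositions + 5 Laplacian-of-Gaussian scales).
#' Feature names follow `<variant>_<family>_<Feature>` (e.g.
#' `wavelet-HHH_firstorder_Skewness`); ordering is fixed across subjects and
#' conditions. Shape features are deliberately absent: in a test-retest
#' design with shared masks they are identical by construction.
#'
#' @param image A `pet_image` (original reconstruction).
#' @param voi A `voi_mask`.
#' @param bin_width Discretization bin width, default 0.15.
#' @param variants Optional precomputed [image_variants()] list (computed
#'   internally when `NULL`); pass this when extracting several VOIs from
#'   one image to avoid re-filtering.
#' @return Named numeric vector of 1,302 features.
#' @export
extract_feature_vector <- function(image, voi, bin_width = 0.15,
                                   variants = NULL) {
  if (is.null(variants)) variants <- image_variants(image)
  stopifnot(identical(names(variants), VARIANT_NAMES))
  parts <- lapply(names(variants), function(vn) {
    f <- extract_features(variants[[vn]], voi, bin_width = bin_width)
    stats::setNames(f, paste0(vn, "_", names(f)))
  })
  unlist(parts)
}

#' Feature vectors for a test/retest pair
#'
#' Extracts the full 1,302-feature bank on the test and the retest image for
#' one VOI. The mask is defined once (on a reference image) and reused on
#' both halves — never re-segmented per half. Discretization is anchored
#' per half independently, mirroring feature extraction run separately on
#' each reconstruction.
#'
#' @param pair A [trt_pair()].
#' @param voi A `voi_mask`.
#' @param bin_width Discretization bin width, default 0.15.
#' @param variants_test,variants_retest Optional precomputed variant lists.
#' @return List with named numeric vectors `test` and `retest` (identical
#'   names and ordering).
#' @export
extract_all <- function(pair, voi, bin_width = 0.15,
                        variants_test = NULL, variants_retest = NULL) {
  stopifnot(inherits(pair, "trt_pair"))
  ft <- extract_feature_vector(pair$test, voi, bin_width, variants_test)
  fr <- extract_feature_vector(pair$retest, voi, bin_width, variants_retest)
  stopifnot(identical(names(ft), names(fr)))
  list(test = ft, retest = fr)
}

#' The versioned feature-name manifest
#'
#' The pinned list of 93 per-variant feature names (and the 1,302 full names
#' over the 14 variants) that extraction is guaranteed to produce, in order.
#'
#' @param full If `TRUE` return all 1,302 `<variant>_<family>_<Feature>`
#'   names; otherwise the 93 `<family>_<Feature>` names.
#' @return Character vector.
#' @export
feature_manifest <- function(full = FALSE) {
  base <- c(
    paste0("firstorder_",
           c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
             "90Percentile", "Maximum", "Mean", "Median",
             "InterquartileRange", "Range", "MeanAbsoluteDeviation",
             "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
             "Kurtosis", "Variance", "Uniformity")),
    paste0("glcm_",
           c("Autocorrelation", "JointAverage", "ClusterProminence",
             "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
             "Id", "Idn", "InverseVariance", "MaximumProbability",
             "SumAverage", "SumEntropy", "SumSquares", "MCC")),
    paste0("gldm_",
           c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
             "GrayLevelNonUniformity", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "GrayLevelVariance",
             "DependenceVariance", "DependenceEntropy",
             "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
             "SmallDependenceLowGrayLevelEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis",
             "LargeDependenceHighGrayLevelEmphasis")),
    paste0("glrlm_",
           c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
             "RunLengthNonUniformityNormalized", "RunPercentage",
             "GrayLevelVariance", "RunVariance", "RunEntropy",
             "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
             "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
             "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")),
    paste0("glszm_",
           c("SmallAreaEmphasis", "LargeAreaEmphasis",
             "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
             "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
             "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
             "ZoneEntropy", "LowGrayLevelZoneEmphasis",
             "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
             "SmallAreaHighGrayLevelEmphasis",
             "LargeAreaLowGrayLevelEmphasis",
             "LargeAreaHighGrayLevelEmphasis")),
    paste0("ngtdm_",
           c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength"))
  )
  if (!full) return(base)
  unlist(lapply(VARIANT_NAMES, function(v) paste0(v, "_", base)),
         use.names = FALSE)
}
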