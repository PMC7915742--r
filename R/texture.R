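#' Gray-level texture matrices for a discretized VOI
#'
#' Builds the five texture-matrix families over a 3D integer level array
#' (0 = outside the mask, 1..Ng inside):
#' * GLCM: symmetric co-occurrence counts at distance 1, one matrix per each
#'   of the 13 unique 3D directions;
#' * GLRLM: run-length counts per direction;
#' * GLSZM: 26-connected equal-level zone sizes;
#' * GLDM: dependence counts (distance 1, tolerance 0); column index is
#'   dependence + 1;
#' * NGTDM: per-level voxel counts and summed absolute differences from the
#'   26-neighborhood mean.
#'
#' @param levels 3D integer array, 0 outside the mask.
#' @param ng Number of gray levels (>= max(levels)).
#' @return List with elements `glcm` (list of 13), `glrlm` (list of 13),
#'   `glszm`, `gldm`, `ngtdm`, and `n_voxels`.
#' @export
texture_matrices <- function(levels, ng = max(levels)) {
  levels <- as.array(levels)
  stopifnot(length(dim(levels)) == 3L)
  d <- as.integer(dim(levels))
  lv <- as.integer(levels)
  n_voxels <- sum(lv > 0L)
  if (n_voxels < 1L) stop("mask is empty", call. = FALSE)
  ng <- as.integer(ng)

  glcm <- cpp_glcm(lv, d, ng)
  glrlm <- cpp_glrlm(lv, d, ng)
  gldm <- cpp_gldm(lv, d, ng)
  ngtdm <- cpp_ngtdm(lv, d, ng)

  lab <- cpp_label_components(lv, d, 26L)
  zsizes <- tabulate(lab)
  zlev <- lv[match(seq_along(zsizes), lab)]
  zmax <- max(zsizes)
  glszm <- matrix(0, nrow = ng, ncol = zmax)
  for (z in seq_along(zsizes)) {
    glszm[zlev[z], zsizes[z]] <- glszm[zlev[z], zsizes[z]] + 1
  }

  list(glcm = glcm, glrlm = glrlm, glszm = glszm, gldm = gldm,
       ngtdm = ngtdm, n_voxels = n_voxels)
}

EPS <- .Machine$double.eps

glcm_features_single <- function(P) {
  tot <- sum(P)
  ng <- nrow(P)
  if (tot == 0) return(NULL)
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p)                       # == py by symmetry
  mu <- sum(seq_len(ng) * px)
  sigma2 <- sum((seq_len(ng) - mu)^2 * px)
  sigma <- sqrt(sigma2)

  # diagonal (difference) and cross-diagonal (sum) probabilities
  kd <- abs(i - j)
  pxmy <- vapply(0:(ng - 1), function(k) sum(p[kd == k]), numeric(1))
  ks <- i + j
  pxpy <- vapply(2:(2 * ng), function(k) sum(p[ks == k]), numeric(1))

  da <- sum((0:(ng - 1)) * pxmy)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hxy <- -sum(p[p > 0] * log2(p[p > 0]))
  pp <- outer(px, px)
  hxy1 <- -sum(p[pp > 0] * log2(pp[pp > 0]))
  hxy2 <- -sum(pp[pp > 0] * log2(pp[pp > 0]))

  occ <- which(px > 0)
  mcc <- if (length(occ) < 2L) 1 else {
    psub <- p[occ, occ, drop = FALSE]
    pxs <- px[occ]
    # Q[a,b] = sum_k p(a,k) p(b,k) / (px(a) px(k))
    q <- sweep(psub %*% t(sweep(psub, 2, pxs, "/")), 1, pxs, "/")
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) < 2L) 1 else sqrt(max(ev[2], 0))
  }

  c(
    Autocorrelation = sum(i * j * p),
    JointAverage = mu,
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sigma2 > 0) (sum(i * j * p) - mu^2) / sigma2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxmy[pxmy > 0] * log2(pxmy[pxmy > 0])),
    DifferenceVariance = sum(((0:(ng - 1)) - da)^2 * pxmy),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    Imc2 = sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0)),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    MaximumProbability = max(p),
    SumAverage = sum((2:(2 * ng)) * pxpy),
    SumEntropy = -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0])),
    SumSquares = sigma2,
    MCC = mcc
  )
}

#' GLCM features (24), averaged over the 13 directions
#' @param glcm_list List of per-direction co-occurrence count matrices.
#' @return Named numeric vector of 24 features (NaN when no voxel pair
#'   exists in any direction).
#' @export
glcm_features <- function(glcm_list) {
  per_dir <- Filter(Negate(is.null), lapply(glcm_list, glcm_features_single))
  nms <- c("Autocorrelation", "JointAverage", "ClusterProminence",
           "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
           "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
           "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
           "Id", "Idn", "InverseVariance", "MaximumProbability",
           "SumAverage", "SumEntropy", "SumSquares", "MCC")
  if (!length(per_dir)) {
    return(stats::setNames(rep(NaN, length(nms)), nms))
  }
  out <- Reduce(`+`, per_dir) / length(per_dir)
  out[nms]
}

rl_features_single <- function(P, n_voxels, prefix) {
  nr <- sum(P)
  if (nr == 0) return(NULL)
  p <- P / nr
  ng <- nrow(P); L <- ncol(P)
  i <- row(p); j <- col(p)
  ivec <- seq_len(ng); jvec <- seq_len(L)
  pg <- rowSums(P); pr <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  vals <- c(
    ShortRunEmphasis = sum(P / j^2) / nr,
    LongRunEmphasis = sum(P * j^2) / nr,
    GrayLevelNonUniformity = sum(pg^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nr^2,
    RunLengthNonUniformity = sum(pr^2) / nr,
    RunLengthNonUniformityNormalized = sum(pr^2) / nr^2,
    RunPercentage = nr / n_voxels,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    RunVariance = sum(p * (j - mu_j)^2),
    RunEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr
  )
  vals
}

#' GLRLM features (16), averaged over the 13 directions
#' @param glrlm_list List of per-direction run-length count matrices.
#' @param n_voxels Number of in-mask voxels.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(glrlm_list, n_voxels) {
  per_dir <- Filter(Negate(is.null),
                    lapply(glrlm_list, rl_features_single, n_voxels = n_voxels))
  nms <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
           "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
           "RunLengthNonUniformityNormalized", "RunPercentage",
           "GrayLevelVariance", "RunVariance", "RunEntropy",
           "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
           "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
           "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  if (!length(per_dir)) return(stats::setNames(rep(NaN, length(nms)), nms))
  out <- Reduce(`+`, per_dir) / length(per_dir)
  out[nms]
}

#' GLSZM features (16)
#' @param P Zone-size count matrix (gray level x zone size).
#' @param n_voxels Number of in-mask voxels.
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(P, n_voxels) {
  nz <- sum(P)
  nms <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
           "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
           "SizeZoneNonUniformityNormalized", "ZonePercentage",
           "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
           "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
           "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
           "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  if (nz == 0) return(stats::setNames(rep(NaN, length(nms)), nms))
  p <- P / nz
  i <- row(P); j <- col(P)
  pg <- rowSums(P); ps <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(
    SmallAreaEmphasis = sum(P / j^2) / nz,
    LargeAreaEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(pg^2) / nz,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nz^2,
    SizeZoneNonUniformity = sum(ps^2) / nz,
    SizeZoneNonUniformityNormalized = sum(ps^2) / nz^2,
    ZonePercentage = nz / n_voxels,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    ZoneVariance = sum(p * (j - mu_j)^2),
    ZoneEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelZoneEmphasis = sum(P / i^2) / nz,
    HighGrayLevelZoneEmphasis = sum(P * i^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz
  )
}

#' GLDM features (14)
#' @param P Dependence count matrix (gray level x (dependence + 1)).
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(P) {
  nz <- sum(P)
  p <- P / nz
  i <- row(P); j <- col(P)
  pg <- rowSums(P); pd <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(
    SmallDependenceEmphasis = sum(P / j^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(pg^2) / nz,
    DependenceNonUniformity = sum(pd^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2) / nz^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    DependenceVariance = sum(p * (j - mu_j)^2),
    DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz
  )
}

#' NGTDM features (5)
#'
#' Degenerate cases follow the conventions of the reference radiomics
#' implementations: `Coarseness` is capped at 1e6 when its denominator is 0;
#' `Contrast` is 0 for a single occupied gray level; `Busyness` and
#' `Strength` are 0 when their denominators vanish.
#'
#' @param M Matrix with columns `n_i` (voxel counts) and `s_i` (summed
#'   absolute neighborhood differences) per gray level.
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(M) {
  n_i <- M[, 1]
  s_i <- M[, 2]
  nvp <- sum(n_i)
  if (nvp == 0) {
    return(c(Coarseness = NaN, Contrast = NaN, Busyness = NaN,
             Complexity = NaN, Strength = NaN))
  }
  p_i <- n_i / nvp
  occ <- which(p_i > 0)
  ngp <- length(occ)
  iv <- seq_along(p_i)

  den_coarse <- sum(p_i * s_i)
  coarseness <- if (den_coarse > 0) 1 / den_coarse else 1e6

  contrast <- if (ngp > 1) {
    sum(outer(p_i[occ], p_i[occ]) * outer(iv[occ], iv[occ], `-`)^2) /
      (ngp * (ngp - 1)) * sum(s_i) / nvp
  } else 0

  # double sum over ordered pairs of occupied levels
  den_busy <- sum(abs(outer(iv[occ] * p_i[occ], iv[occ] * p_i[occ], `-`)))
  busyness <- if (den_busy > 0) sum(p_i * s_i) / den_busy else 0

  cplx <- 0
  for (a in occ) for (b in occ) {
    cplx <- cplx + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
      (p_i[a] + p_i[b])
  }

  den_str <- sum(s_i)
  strength <- if (den_str > 0) {
    sum(outer(p_i[occ], p_i[occ], `+`) * outer(iv[occ], iv[occ], `-`)^2) /
      den_str
  } else 0

  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = cplx / nvp, Strength = strength)
}
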