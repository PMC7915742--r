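#' Z-score normalize a feature table
#'
#' Centers each feature column to mean 0 and scales to unit population
#' standard deviation (divisor n, the convention of the scientific-Python
#' `zscore`, not R's sample-SD `scale()`). Zero-variance and non-finite
#' columns are dropped with a warning.
#'
#' @param table Numeric matrix, subjects x features.
#' @return Z-scored matrix (possibly fewer columns); dropped column names in
#'   attribute `"dropped"`.
#' @export
zscore_features <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L) stop("need >= 2 subjects to z-score", call. = FALSE)
  mu <- colMeans(table)
  sd_pop <- sqrt(colMeans(sweep(table, 2, mu)^2))
  bad <- !is.finite(sd_pop) | sd_pop == 0 | colSums(!is.finite(table)) > 0
  if (any(bad)) {
    warning(sprintf("dropping %d constant or non-finite feature column(s)",
                    sum(bad)))
  }
  out <- sweep(sweep(table[, !bad, drop = FALSE], 2, mu[!bad]), 2,
               sd_pop[!bad], "/")
  attr(out, "dropped") <- colnames(table)[bad]
  out
}

#' Ward hierarchical clustering of subjects
#'
#' Agglomerative clustering under Ward's variance-minimization criterion on
#' squared Euclidean distances (implemented via `hclust(method =
#' "ward.D2")` on Euclidean distances; merge heights `h` satisfy
#' `h^2 = 2 x` the within-cluster variance increase of the merge). The cut
#' into `n_clusters` gives the subject assignments.
#'
#' @param table Z-scored feature matrix, subjects x features (rownames =
#'   subject ids).
#' @param n_clusters Number of clusters at the cut, default 2.
#' @return List: `hclust` (the merge tree), `assignments` (named integer
#'   vector), `heights`.
#' @export
ward_cluster <- function(table, n_clusters = 2L) {
  table <- as.matrix(table)
  if (nrow(table) < n_clusters) {
    stop("fewer subjects than requested clusters", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(table, method = "euclidean"),
                      method = "ward.D2")
  assignments <- stats::cutree(hc, k = n_clusters)
  list(hclust = hc, assignments = assignments, heights = hc$height)
}

#' Genotype composition of clusters
#'
#' Per-cluster label counts and majority-class purity.
#'
#' @param assignments Named integer vector (subject -> cluster id).
#' @param labels Genotype label per subject, same order/names.
#' @return Data frame: cluster, n, one count column per label, majority
#'   label, purity_pct.
#' @export
genotype_composition <- function(assignments, labels) {
  if (length(assignments) != length(labels)) {
    stop("every subject needs a label", call. = FALSE)
  }
  if (any(is.na(labels))) stop("unknown (NA) genotype label", call. = FALSE)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  rows <- lapply(sort(unique(assignments)), function(cl) {
    sub <- labels[assignments == cl]
    counts <- vapply(lev, function(l) sum(sub == l), integer(1))
    maj <- lev[which.max(counts)]
    df <- data.frame(cluster = cl, n = length(sub), stringsAsFactors = FALSE)
    for (l in lev) df[[paste0("n_", l)]] <- counts[[l]]
    df$majority <- maj
    df$purity_pct <- 100 * max(counts) / length(sub)
    df
  })
  do.call(rbind, rows)
}

#' Overall cluster purity
#'
#' Fraction (0-1) of subjects belonging to the majority label of their
#' cluster — the statistic compared against a permutation null.
#'
#' @inheritParams genotype_composition
#' @return Scalar in (0, 1].
#' @export
cluster_purity <- function(assignments, labels) {
  labels <- as.character(labels)
  total <- 0L
  for (cl in unique(assignments)) {
    sub <- labels[assignments == cl]
    total <- total + max(table(sub))
  }
  total / length(labels)
}

#' Permutation null for cluster purity
#'
#' Recomputes the purity of fixed cluster assignments under random
#' permutations of the genotype labels.
#'
#' @inheritParams genotype_composition
#' @param n_perm Number of permutations, default 1000.
#' @param seed Integer seed.
#' @return List: `observed`, `null` (vector of permuted purities),
#'   `p_value` (one-sided, with +1 continuity).
#' @export
purity_permutation_test <- function(assignments, labels, n_perm = 1000L,
                                    seed = 1L) {
  observed <- cluster_purity(assignments, labels)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    cluster_purity(assignments, sample(labels))
  }, numeric(1)))
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed)) / (n_perm + 1))
}
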