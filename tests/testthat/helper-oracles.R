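# Independent brute-force oracles. These deliberately use naive enumeration
# (voxel-pair loops, recursive flood fill, explicit variance bookkeeping) and
# never call the package's compiled kernels.

oracle_dirs13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# Symmetric co-occurrence counts: enumerate every in-mask voxel and its
# distance-1 neighbor along +dir; count the pair in both orders.
oracle_glcm <- function(lev, ng) {
  d <- dim(lev)
  lapply(seq_len(13), function(k) {
    dir <- oracle_dirs13[k, ]
    m <- matrix(0, ng, ng)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      i <- lev[x, y, z]
      if (i == 0) next
      q <- c(x, y, z) + dir
      if (!in_grid(q, d)) next
      j <- lev[q[1], q[2], q[3]]
      if (j == 0) next
      m[i, j] <- m[i, j] + 1
      m[j, i] <- m[j, i] + 1
    }
    m
  })
}

# Run-length counts: walk every maximal run per direction.
oracle_glrlm <- function(lev, ng) {
  d <- dim(lev)
  lmax <- max(d)
  lapply(seq_len(13), function(k) {
    dir <- oracle_dirs13[k, ]
    m <- matrix(0, ng, lmax)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      v <- lev[x, y, z]
      if (v == 0) next
      p <- c(x, y, z) - dir
      if (in_grid(p, d) && lev[p[1], p[2], p[3]] == v) next  # not a run start
      len <- 1
      q <- c(x, y, z) + dir
      while (in_grid(q, d) && lev[q[1], q[2], q[3]] == v) {
        len <- len + 1
        q <- q + dir
      }
      m[v, len] <- m[v, len] + 1
    }
    m
  })
}

# 26-connected equal-level zones by repeated flood fill over index sets.
oracle_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, dim = d)
  zones <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (lev[x, y, z] == 0 || seen[x, y, z]) next
    val <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (!in_grid(q, d)) next
        if (!seen[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == val) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = val, size = size)
  }
  zones
}

oracle_glszm <- function(lev, ng) {
  zones <- oracle_zones(lev)
  zmax <- max(vapply(zones, `[[`, numeric(1), "size"))
  m <- matrix(0, ng, zmax)
  for (zn in zones) m[zn["level"], zn["size"]] <- m[zn["level"], zn["size"]] + 1
  m
}

oracle_gldm <- function(lev, ng) {
  d <- dim(lev)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  m <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    v <- lev[x, y, z]
    if (v == 0) next
    dep <- 0
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (in_grid(q, d) && lev[q[1], q[2], q[3]] == v) dep <- dep + 1
    }
    m[v, dep + 1] <- m[v, dep + 1] + 1
  }
  m
}

oracle_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  m <- matrix(0, ng, 2)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    v <- lev[x, y, z]
    if (v == 0) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (in_grid(q, d) && lev[q[1], q[2], q[3]] != 0) {
        nb <- c(nb, lev[q[1], q[2], q[3]])
      }
    }
    if (!length(nb)) next
    m[v, 1] <- m[v, 1] + 1
    m[v, 2] <- m[v, 2] + abs(v - mean(nb))
  }
  m
}

# Two-way ANOVA ICC(A,1) by explicit sums of squares (loops, no matrix
# shortcuts) - the oracle for icc_a1.
oracle_icc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ss_r <- 0; ss_c <- 0; ss_t <- 0
  for (i in 1:n) ss_r <- ss_r + k * (mean(m[i, ]) - gm)^2
  for (j in 1:k) ss_c <- ss_c + n * (mean(m[, j]) - gm)^2
  for (i in 1:n) for (j in 1:k) ss_t <- ss_t + (m[i, j] - gm)^2
  msr <- ss_r / (n - 1)
  msc <- ss_c / (k - 1)
  mse <- (ss_t - ss_r - ss_c) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Greedy Ward agglomeration with explicit within-cluster variance
# bookkeeping; returns the sequence of merge costs as ward.D2-scale heights
# sqrt(2 * delta(SSE)).
oracle_ward_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) x[i, , drop = FALSE])
  heights <- numeric(0)
  sse <- function(m) sum(sweep(m, 2, colMeans(m))^2)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in 1:(length(clusters) - 1)) for (b in (a + 1):length(clusters)) {
      merged <- rbind(clusters[[a]], clusters[[b]])
      delta <- sse(merged) - sse(clusters[[a]]) - sse(clusters[[b]])
      if (delta < best[1]) best <- c(delta, a, b)
    }
    heights <- c(heights, sqrt(2 * best[1]))
    merged <- rbind(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
    clusters[[best[2]]] <- merged
  }
  heights
}

# Random discretized-level test volumes: a blob-ish mask with ng levels on a
# small grid; 0 outside the mask.
random_levels <- function(dim3, ng, p_mask = 0.7) {
  mask <- array(stats::runif(prod(dim3)) < p_mask, dim = dim3)
  lev <- array(0L, dim = dim3)
  lev[mask] <- sample.int(ng, sum(mask), replace = TRUE)
  lev
}
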