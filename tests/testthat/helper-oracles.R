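# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition with naive loops, never
# through the package's own code paths.

# nearest-neighbour ECDF from each reference point to the target set
oracle_cross_g <- function(ref, tgt, r_grid) {
  if (nrow(ref) == 0 || nrow(tgt) == 0) return(rep(0, length(r_grid)))
  nn <- apply(ref, 1, function(p)
    min(sqrt((tgt[, 1] - p[1])^2 + (tgt[, 2] - p[2])^2)))
  sapply(r_grid, function(r) sum(nn <= r) / nrow(ref))
}

# plain trapezoid over the grid restricted to [0, r_cut]
oracle_trapezoid <- function(r, G, r_cut) {
  keep <- which(r <= r_cut + 1e-12)
  total <- 0
  for (i in keep[-length(keep)])
    total <- total + (r[i + 1] - r[i]) * (G[i] + G[i + 1]) / 2
  total
}

# O(n^2) pair counts with inclusive boundary and optional self-exclusion
oracle_pair_counts <- function(ref, tgt, radius, self = FALSE) {
  sapply(seq_len(nrow(ref)), function(i) {
    d <- sqrt((tgt[, 1] - ref[i, 1])^2 + (tgt[, 2] - ref[i, 2])^2)
    n <- sum(d <= radius + 1e-12)
    if (self) n <- n - 1L
    n
  })
}

# exact two-sided rank-sum p by bitmask enumeration of every assignment
# (independent of the combn/shift paths inside the package)
oracle_wilcoxon_enum <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  M <- as.matrix(expand.grid(rep(list(0:1), n)))   # every 0/1 assignment
  M <- M[rowSums(M) == nx, , drop = FALSE]
  sums <- as.vector(M %*% r)
  pl <- mean(sums <= W + 1e-9)
  pg <- mean(sums >= W - 1e-9)
  min(1, 2 * min(pl, pg))
}

# BH step-up applied directly from its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  pmin(adj, 1)
}

# repeated-measures ANOVA F from the sum-of-squares decomposition
oracle_rm_anova_F <- function(y) {   # y already transformed, complete matrix
  ns <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ss_region <- ns * sum((colMeans(y) - grand)^2)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_region - ss_subj
  (ss_region / (k - 1)) / (ss_err / ((ns - 1) * (k - 1)))
}

# exhaustive pixel-distance label expansion (nearest labelled pixel within
# radius; lower label id on exact ties)
oracle_expand <- function(labels, pixel_size, radius) {
  ny <- nrow(labels); nx <- ncol(labels)
  rpx2 <- (radius / pixel_size)^2 + 1e-9
  lab_idx <- which(labels > 0, arr.ind = TRUE)
  out <- labels
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (labels[i, j] > 0) next
    d2 <- (lab_idx[, 1] - i)^2 + (lab_idx[, 2] - j)^2
    ok <- d2 <= rpx2
    if (!any(ok)) next
    dmin <- min(d2[ok])
    cands <- labels[lab_idx[ok & d2 <= dmin + 1e-12, , drop = FALSE]]
    out[i, j] <- min(cands)
  }
  out
}

# direct per-pixel disc rasterization for one or more cells
oracle_render <- function(xy, pixel_size, radius, nx, ny) {
  out <- matrix(0L, ny, nx)
  best <- matrix(Inf, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    px <- (j - 0.5) * pixel_size; py <- (i - 0.5) * pixel_size
    for (k in seq_len(nrow(xy))) {
      d2 <- (px - xy[k, 1])^2 + (py - xy[k, 2])^2
      if (d2 <= radius^2 + 1e-12 && d2 < best[i, j]) {
        best[i, j] <- d2; out[i, j] <- k
      }
    }
  }
  out
}

# random small label mask: a few single-pixel and square seeds
random_mask <- function(seed, ny = 48, nx = 48, n_labels = 8,
                        pixel_size = 1) {
  set.seed(seed)
  m <- matrix(0L, ny, nx)
  for (k in seq_len(n_labels)) {
    sz <- sample(1:3, 1)
    i <- sample(seq_len(ny - sz), 1); j <- sample(seq_len(nx - sz), 1)
    block <- m[i:(i + sz - 1), j:(j + sz - 1)]
    block[block == 0L] <- k
    m[i:(i + sz - 1), j:(j + sz - 1)] <- block
  }
  label_mask(m, pixel_size)
}

# small quick config for pipeline-level tests
small_config <- function(seed, ...) {
  simulation_config(window_width = 450, window_height = 300,
                    seed = seed, ...)
}
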