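# Independent brute-force oracles used to check the implementations.

oracle_sensitivity <- function(det, truth) {
  n_both <- 0L
  n_truth <- 0L
  for (i in seq_along(truth$values)) {
    if (truth$values[i]) {
      n_truth <- n_truth + 1L
      if (det$values[i]) n_both <- n_both + 1L
    }
  }
  n_both / n_truth
}

oracle_specificity <- function(det, truth, brain) {
  n_brain <- 0L
  n_truth <- 0L
  n_flagged <- 0L
  for (i in seq_along(brain$values)) {
    if (brain$values[i]) {
      n_brain <- n_brain + 1L
      if (det$values[i] || truth$values[i]) n_flagged <- n_flagged + 1L
    }
    if (truth$values[i]) n_truth <- n_truth + 1L
  }
  (n_brain - n_flagged) / (n_brain - n_truth)
}

oracle_dice <- function(a, b) {
   2 * sum(a$values & b$values) / (sum(a$values) + sum(b$values))
}

# world coordinates (mm) of the set voxels of a mask
set_voxel_coords <- function(mask) {
  g <- mask$geometry
  idx <- which(mask$values, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
}

# 6-neighbourhood surface by explicit neighbour loop
oracle_surface <- function(mask) {
  v <- mask$values
  dims <- dim(v)
  out <- array(FALSE, dims)
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      for (k in seq_len(dims[3])) {
        if (!v[i, j, k]) next
        nb <- c(
          if (i > 1) v[i - 1, j, k] else FALSE,
          if (i < dims[1]) v[i + 1, j, k] else FALSE,
          if (j > 1) v[i, j - 1, k] else FALSE,
          if (j < dims[2]) v[i, j + 1, k] else FALSE,
          if (k > 1) v[i, j, k - 1] else FALSE,
          if (k < dims[3]) v[i, j, k + 1] else FALSE
        )
        if (!all(nb)) out[i, j, k] <- TRUE
      }
    }
  }
  binary_mask(out, mask$geometry)
}

# all-pairs symmetric maximum surface distance
oracle_max_surface_distance <- function(a, b) {
  if (!any(a$values) || !any(b$values)) return(NA_real_)
  sa <- set_voxel_coords(oracle_surface(a))
  sb <- set_voxel_coords(oracle_surface(b))
  d2 <- outer(rowSums(sa^2), rowSums(sb^2), "+") - 2 * sa %*% t(sb)
  d2[d2 < 0] <- 0
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

# brute-force metric expansion: distance to nearest set voxel center
oracle_expand <- function(mask, radius_mm) {
  pts <- set_voxel_coords(mask)
  g <- mask$geometry
  centers <- tumorburden:::voxel_centers(g)
  d2 <- outer(rowSums(centers^2), rowSums(pts^2), "+") - 2 * centers %*% t(pts)
  keep <- apply(d2, 1, min) <= radius_mm^2 + 1e-9
  binary_mask(array(keep, g$shape), g)
}

# exact signed-rank two-sided p by explicit 2^m sign enumeration
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# exact rank-sum two-sided p by explicit choose(n, n1) enumeration
oracle_rank_sum_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]))
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
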