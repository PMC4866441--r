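# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: patches come from explicit coordinate
# enumeration, kernels from scalar loops, Sinkhorn from dense alternating
# normalization, and the global filter from a dense eigendecomposition.

rand_volume <- function(shape, seed = 1, voxel_size = c(1, 1, 1)) {
  set.seed(seed)
  as_volume(array(runif(prod(shape)), dim = shape), voxel_size = voxel_size)
}

# scalar mirror reflection (no edge repeat), applied iteratively
oracle_reflect <- function(c, n) {
  if (n == 1) return(1)
  while (c < 1 || c > n) {
    if (c < 1) c <- 2 - c
    if (c > n) c <- 2 * n - c
  }
  c
}

# patch by explicit nested loops, first axis fastest
oracle_patch <- function(vol, i, j, k, r) {
  d <- vol$shape
  out <- numeric(0)
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    out <- c(out, vol$data[oracle_reflect(i + dx, d[1]),
                           oracle_reflect(j + dy, d[2]),
                           oracle_reflect(k + dz, d[3])])
  }
  out
}

# dense n x n patch-affinity matrix by double loop over oracle patches
oracle_affinity <- function(vol, radius, h) {
  n <- prod(vol$shape)
  L <- (2 * radius + 1)^3
  P <- matrix(0, n, L)
  for (idx in seq_len(n)) {
    cc <- vol_coords(vol$shape, idx)
    P[idx, ] <- oracle_patch(vol, cc[1], cc[2], cc[3], radius)
  }
  D2 <- as.matrix(stats::dist(P))^2
  K <- exp(-D2 / (L * h^2))
  diag(K) <- 1
  dimnames(K) <- NULL
  K
}

# dense symmetric Sinkhorn limit: alternating row/column normalization on
# the scaling vectors; the doubly stochastic diagonal scaling of a symmetric
# positive matrix is unique, so any convergent iteration reaches it. After
# row normalization rows sum to 1 exactly, so convergence is monitored on
# the column sums; the matrix is only formed (and re-symmetrized) at the end.
oracle_sinkhorn <- function(K, tol = 1e-12, max_iter = 5000) {
  r <- rep(1, nrow(K))
  c <- rep(1, ncol(K))
  for (it in seq_len(max_iter)) {
    r <- 1 / drop(K %*% c)
    colres <- max(abs(c * drop(crossprod(K, r)) - 1))
    if (colres < tol) break
    c <- 1 / drop(crossprod(K, r))
  }
  W <- r * t(c * K)
  (W + t(W)) / 2
}

# dense global filter output V_m E^k V_m' y from an explicit symmetric W
oracle_filter <- function(W, y, k, m = nrow(W)) {
  eg <- eigen(W, symmetric = TRUE)
  V <- eg$vectors[, seq_len(m), drop = FALSE]
  lam <- pmin(pmax(eg$values[seq_len(m)], 0), 1)
  drop(V %*% (lam^k * drop(crossprod(V, y))))
}
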