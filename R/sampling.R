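#' Landmark voxel selection
#'
#' The Nystrom approximation needs `l` landmark voxels whose kernel columns
#' are computed exactly. `uniform_sample()` draws them uniformly without
#' replacement; `kmeans_sample()` clusters per-voxel patch features with
#' k-means (`k = l`) and returns, for each cluster, the real voxel whose
#' feature vector is nearest the centroid. Clustering concentrates landmarks
#' in informative tissue instead of the (large, homogeneous) background and
#' spreads them over the full dynamic range.
#'
#' @param vol a [as_volume()] object.
#' @param l number of landmarks, `1 <= l <= n`.
#' @param seed integer seed; the same `(volume, scheme, l, seed)` always
#'   yields the same landmark set.
#' @param spec a [kernel_spec()]; its patch radius defines the k-means
#'   feature vectors (radius 0 recovers clustering on raw intensities).
#' @param iter_max k-means iteration cap (Lloyd iterations run until the
#'   assignment is stable or this cap is hit).
#' @return a `gmrid_sample_set` with fields `indices`, `scheme`, `l`, `seed`
#'   and (k-means only) `cluster_labels`.
#' @export
uniform_sample <- function(vol, l, seed = 1L) {
  vol <- as_volume(vol)
  n <- n_voxels(vol)
  l <- as.integer(l)
  if (l < 1L || l > n) stop_contract("need 1 <= l <= n = %d", n)
  idx <- with_seed(seed, sample.int(n, l))
  sample_set(idx, "uniform", seed)
}

sample_set <- function(indices, scheme, seed, cluster_labels = NULL) {
  structure(list(indices = as.integer(indices), scheme = scheme,
                 l = length(indices), seed = as.integer(seed),
                 cluster_labels = cluster_labels),
            class = "gmrid_sample_set")
}

# k-means++ seeding over the rows of X; returns row indices.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[centers[1L], ], "-")^2)
  for (j in seq_len(k - 1L)) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) <= 0)
      cand <- sample.int(n, 1L)
    else
      cand <- sample.int(n, 1L, prob = p)
    centers[j + 1L] <- cand
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[cand, ], "-")^2))
  }
  unique_fix(centers, n)
}

# ensure distinct seeding rows (duplicates possible on degenerate data)
unique_fix <- function(centers, n) {
  dup <- duplicated(centers)
  while (any(dup)) {
    centers[dup] <- sample.int(n, sum(dup))
    dup <- duplicated(centers)
  }
  centers
}

#' @rdname uniform_sample
#' @export
kmeans_sample <- function(vol, l, spec = kernel_spec(), seed = 1L,
                          iter_max = 100L) {
  vol <- as_volume(vol)
  n <- n_voxels(vol)
  l <- as.integer(l)
  if (l < 1L || l > n) stop_contract("need 1 <= l <= n = %d", n)
  X <- patch_matrix(vol, spec$patch_radius)
  if (l == n) return(sample_set(seq_len(n), "kmeans", seed,
                                cluster_labels = seq_len(n)))
  res <- with_seed(seed, {
    init <- kmeanspp_init(X, l)
    run <- function(alg) tryCatch(
      suppressWarnings(stats::kmeans(X, centers = X[init, , drop = FALSE],
                                     iter.max = iter_max, algorithm = alg)),
      error = function(e) NULL)
    km <- run("Lloyd")
    if (is.null(km)) km <- run("MacQueen")
    if (is.null(km)) {
      # degenerate data (e.g. many identical patch vectors): fall back to
      # the k-means++ seeding itself, with nearest-center assignment
      centers <- X[init, , drop = FALSE]
      cs <- rowSums(centers^2)
      lab <- max.col(-(outer(rowSums(X^2), cs, "+") - 2 * X %*% t(centers)),
                     ties.method = "first")
      km <- list(centers = centers, cluster = lab)
    }
    km
  })
  centers <- res$centers
  labels <- res$cluster
  idx <- integer(l)
  for (c in seq_len(l)) {
    members <- which(labels == c)
    if (length(members) == 0L) next   # empty cluster, handled below
    d2 <- colSums((t(X[members, , drop = FALSE]) - centers[c, ])^2)
    idx[c] <- members[which.min(d2)]
  }
  empty <- which(idx == 0L)
  if (length(empty)) {
    # re-seed each empty cluster from the voxel farthest from the chosen
    # landmarks (maximin), keeping exactly l distinct landmarks; the
    # min-distance vector is maintained incrementally
    message(sprintf("kmeans_sample: re-seeding %d empty cluster(s)",
                    length(empty)))
    chosen <- idx[idx > 0L]
    dmin <- rep(Inf, n)
    for (j in chosen)
      dmin <- pmin(dmin, colSums((t(X) - X[j, ])^2))
    dmin[chosen] <- -Inf
    for (c in empty) {
      pick <- which.max(dmin)
      idx[c] <- pick
      dmin <- pmin(dmin, colSums((t(X) - X[pick, ])^2))
      dmin[pick] <- -Inf
    }
  }
  stopifnot(!anyDuplicated(idx))
  sample_set(idx, "kmeans", seed, cluster_labels = labels)
}

#' Relative accuracy of a low-rank kernel approximation
#'
#' Scores an approximation `K_approx` of a symmetric PSD matrix `K` against
#' the optimal rank-`r` truncation `K_r` (truncated eigendecomposition):
#' `100 * ||K - K_r||_F / ||K - K_approx||_F`. By the Eckart-Young theorem
#' the score lies in `[0, 100]` for any rank-`<= r` approximant and equals
#' 100 exactly at the optimum. If both errors vanish (`K` itself has rank
#' `<= r` and is reproduced exactly) the score is 100 by convention.
#'
#' @param K symmetric positive semidefinite matrix.
#' @param r target rank, `1 <= r <= nrow(K)`.
#' @param K_approx approximation of the same shape, rank at most `r`.
#' @return percent score in `[0, 100]`.
#' @export
relative_accuracy <- function(K, r, K_approx) {
  K <- as.matrix(K); K_approx <- as.matrix(K_approx)
  if (!all(dim(K) == dim(K_approx)))
    stop_contract("K and K_approx must have the same shape")
  nK <- nrow(K)
  r <- as.integer(r)
  if (r < 1L || r > nK) stop_contract("need 1 <= r <= %d", nK)
  eg <- eigen(K, symmetric = TRUE)
  keep <- seq_len(r)
  Kr <- eg$vectors[, keep, drop = FALSE] %*%
    (eg$values[keep] * t(eg$vectors[, keep, drop = FALSE]))
  num <- sqrt(sum((K - Kr)^2))
  den <- sqrt(sum((K - K_approx)^2))
  if (den == 0) return(100)
  min(100 * num / den, 100)
}
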