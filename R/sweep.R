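#' Sampling-scheme accuracy sweep
#'
#' Compares landmark sampling schemes by the relative accuracy of the
#' rank-`r` Nystrom reconstruction of the dense patch-affinity matrix, over
#' a grid of sampling rates and seeds. The dense kernel and its optimal
#' rank-`r` truncation error are computed once and shared by every run;
#' only the sampled approximation changes. Dense, so test scale only.
#'
#' @param vol a [as_volume()] object (or 3D array); `n` must stay within
#'   `dense_limit`.
#' @param rates sampling rates `l / n` in `(0, 1]`.
#' @param rank truncation rank `r` for both the exact and the approximated
#'   reconstruction.
#' @param seeds integer vector of seeds (one full sweep per seed).
#' @param schemes subset of `c("uniform", "kmeans")`.
#' @param spec a [kernel_spec()].
#' @param dense_limit refuse volumes with more voxels than this.
#' @return data frame with columns `scheme`, `rate`, `seed`, `l`,
#'   `relative_accuracy`.
#' @export
sampling_sweep <- function(vol, rates = c(0.05, 0.1, 0.2), rank = 20L,
                           seeds = 1:10, schemes = c("uniform", "kmeans"),
                           spec = kernel_spec(), dense_limit = 5000L) {
  vol <- as_volume(vol)
  n <- n_voxels(vol)
  if (n > dense_limit)
    stop_contract("sweep needs the dense kernel; n = %d exceeds dense_limit = %d",
                  n, dense_limit)
  schemes <- match.arg(schemes, several.ok = TRUE)
  rank <- as.integer(rank)

  full <- compute_kernel_blocks(vol, sample_set(seq_len(n), "uniform", 0L), spec)
  K <- full$M1
  eg <- eigen(K, symmetric = TRUE)
  keep <- seq_len(rank)
  Kr <- eg$vectors[, keep, drop = FALSE] %*%
    (eg$values[keep] * t(eg$vectors[, keep, drop = FALSE]))
  err_opt <- sqrt(sum((K - Kr)^2))

  rows <- list()
  for (scheme in schemes) for (rate in rates) for (seed in seeds) {
    l <- max(ceiling(rate * n), rank)
    samp <- if (scheme == "kmeans") kmeans_sample(vol, l, spec, seed)
            else uniform_sample(vol, l, seed)
    blocks <- compute_kernel_blocks(vol, samp, spec)
    # best rank-r truncation of the full (rank-l) Nystrom reconstruction:
    # the r leading eigenpairs of the orthogonalized approximation
    os <- one_shot_spectrum(blocks$M1, blocks$M12, rank)
    inv <- order(blocks$sample_order)
    Ka <- (os$V %*% (os$E * t(os$V)))[inv, inv]
    err <- sqrt(sum((K - Ka)^2))
    ra <- if (err == 0) 100 else min(100 * err_opt / err, 100)
    rows[[length(rows) + 1L]] <-
      data.frame(scheme = scheme, rate = rate, seed = seed, l = l,
                 relative_accuracy = ra)
  }
  do.call(rbind, rows)
}
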