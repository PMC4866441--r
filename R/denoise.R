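#' Noise model
#'
#' @param family `"gaussian"` (additive) or `"rician"` (magnitude).
#' @param sigma noise standard deviation on the rescaled `[0, 1]` intensity
#'   range (a noise level quoted as a percentage of the maximum intensity
#'   maps to `pct / 100`).
#' @return a `gmrid_noise_model` object.
#' @export
noise_model <- function(family = c("gaussian", "rician"), sigma) {
  family <- match.arg(family)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop_contract("sigma must be a positive scalar")
  structure(list(family = family, sigma = as.numeric(sigma)),
            class = "gmrid_noise_model")
}

#' Project data onto the filter spectrum
#'
#' Computes the spectral coefficients `b_j = v_j' y` and the shrunken
#' squared-signal estimates `max(b_j^2 - sigma^2, 0)`. Under white noise of
#' standard deviation `sigma` and orthonormal `v_j`, `E[b_j^2]` equals the
#' clean signal energy in mode `j` plus `sigma^2`, so the subtraction is an
#' unbiased (then nonnegativity-truncated) estimate of the clean `b_j^2`
#' that the risk proxy needs.
#'
#' @param spectrum a [orthogonalize_filter()] result.
#' @param y flattened volume in canonical voxel order, length `n`.
#' @param sigma noise standard deviation on the scale of `y` (0 disables
#'   shrinkage).
#' @return a `gmrid_projection` with `coeffs` and `shrunk_b2`.
#' @export
project <- function(spectrum, y, sigma = 0) {
  stopifnot(inherits(spectrum, "gmrid_filter_spectrum"))
  if (length(y) != spectrum$n)
    stop_contract("length(y) = %d does not match spectrum n = %d",
                  length(y), spectrum$n)
  if (sigma < 0) stop_contract("sigma must be >= 0")
  ys <- y[spectrum$sample_order]
  coeffs <- drop(crossprod(spectrum$eigvecs, ys))
  structure(list(coeffs = coeffs,
                 shrunk_b2 = pmax(coeffs^2 - sigma^2, 0)),
            class = "gmrid_projection")
}

#' Risk proxy of the truncated diffusion filter
#'
#' The mean squared error of the rank-`m`, diffusion-`k` filter decomposes
#' as a constant (the clean signal energy) plus
#' `sum_{j<=m} ((lambda_j^{2k} - 2 lambda_j^k) b_j^2 + sigma^2 lambda_j^{2k})`.
#' Only this variable part is returned: the constant does not depend on
#' `(k, m)` and so cannot change the argmin.
#'
#' @param eigvals filter eigenvalues in `[0, 1]`, descending.
#' @param proj a [project()] result (its `shrunk_b2` estimates `b_j^2`).
#' @param sigma noise standard deviation.
#' @param params list with diffusion exponent `k >= 0` and truncation rank
#'   `m` (see [select_diffusion()]).
#' @return scalar value of the variable risk part.
#' @export
estimate_mse_proxy <- function(eigvals, proj, sigma, params) {
  if (sigma < 0) stop_contract("sigma must be >= 0")
  m <- as.integer(params$m)
  if (m < 1L || m > length(eigvals))
    stop_contract("m must lie in [1, %d]", length(eigvals))
  lam_k <- eigvals[seq_len(m)]^params$k
  b2 <- proj$shrunk_b2[seq_len(m)]
  sum((lam_k^2 - 2 * lam_k) * b2 + sigma^2 * lam_k^2)
}

#' Select diffusion strength and truncation rank
#'
#' Exhaustive grid search for the `(k, m)` pair minimizing
#' [estimate_mse_proxy()]; ties are broken toward smaller `k`, then smaller
#' `m`. With `sigma = 0` every retained mode can only reduce the proxy, so
#' the selection collapses to the weakest smoothing (`min(k_grid)`) and the
#' full rank (`max(m_grid)`).
#'
#' @param eigvals filter eigenvalues in `[0, 1]`, descending.
#' @param proj a [project()] result.
#' @param sigma noise standard deviation.
#' @param k_grid nonnegative diffusion exponents to search.
#' @param m_grid truncation ranks to search (subset of `1:length(eigvals)`).
#' @return list with `k`, `m`, the attained `value`, and `curve`, a data
#'   frame of the objective over the whole grid.
#' @export
select_diffusion <- function(eigvals, proj, sigma,
                             k_grid = c(0, seq(0.5, 8, by = 0.5)),
                             m_grid = seq_along(eigvals)) {
  if (length(k_grid) == 0L || length(m_grid) == 0L)
    stop_contract("k_grid and m_grid must be nonempty")
  if (any(k_grid < 0)) stop_contract("k_grid values must be >= 0")
  m_grid <- as.integer(m_grid)
  if (any(m_grid < 1L) || any(m_grid > length(eigvals)))
    stop_contract("m_grid must be a subset of 1..%d", length(eigvals))
  k_grid <- sort(k_grid)
  m_grid <- sort(m_grid)
  b2 <- proj$shrunk_b2
  best <- NULL
  curve <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    lam_k <- eigvals^k
    terms <- (lam_k^2 - 2 * lam_k) * b2 + sigma^2 * lam_k^2
    cum <- cumsum(terms)
    vals <- cum[m_grid]
    curve[[i]] <- data.frame(k = k, m = m_grid, value = vals)
    j <- which.min(vals)   # first minimum -> smallest m on ties
    if (is.null(best) || vals[j] < best$value) {
      best <- list(k = k, m = m_grid[j], value = vals[j])
    }
  }
  best$curve <- do.call(rbind, curve)
  best
}

#' Apply the truncated diffusion filter
#'
#' Computes `V_m diag(lambda_j^k) V_m' y` without materializing the `n x n`
#' filter. Linear in `y`.
#'
#' @param spectrum a [orthogonalize_filter()] result.
#' @param y flattened volume in canonical voxel order.
#' @param params list with diffusion exponent `k` and truncation rank `m`.
#' @return filtered vector, canonical voxel order, length `n`.
#' @export
apply_global_filter <- function(spectrum, y, params) {
  stopifnot(inherits(spectrum, "gmrid_filter_spectrum"))
  if (length(y) != spectrum$n)
    stop_contract("length(y) = %d does not match spectrum n = %d",
                  length(y), spectrum$n)
  m <- as.integer(params$m)
  if (m < 1L || m > spectrum$m)
    stop_contract("m must lie in [1, %d]", spectrum$m)
  V <- spectrum$eigvecs[, seq_len(m), drop = FALSE]
  lam_k <- spectrum$eigvals[seq_len(m)]^params$k
  ys <- y[spectrum$sample_order]
  out_s <- drop(V %*% (lam_k * drop(crossprod(V, ys))))
  out <- numeric(spectrum$n)
  out[spectrum$sample_order] <- out_s
  out
}

#' Global denoising of a 3D volume
#'
#' Runs the full pipeline: rescale to `[0, 1]`; (Rician only) variance
#' stabilization; landmark sampling; sampled kernel blocks; Nystrom-based
#' Sinkhorn symmetrization; orthogonalized spectrum; risk-driven selection
#' of diffusion exponent and truncation rank; spectral filtering; (Rician
#' only) inverse stabilization; restore original intensity units.
#'
#' @param vol a [as_volume()] object (or 3D array).
#' @param noise a [noise_model()].
#' @param kernel a [kernel_spec()]; the default (`NULL`) ties the bandwidth
#'   to the noise level, `h = max(sigma, 0.05)`, following the non-local
#'   means convention `h^2 = 2 beta sigma^2` with `beta = 1/2`.
#' @param scheme landmark sampling scheme, `"kmeans"` or `"uniform"`.
#' @param rate landmark sampling rate in `(0, 1]`; the landmark count is
#'   `l = max(ceiling(rate * n), rank)` (clamped to `n`, with a warning when
#'   the rate alone would give fewer landmarks than the rank).
#' @param rank retained Nystrom/spectrum rank (the search space for the
#'   truncation parameter).
#' @param seed integer seed controlling all randomness.
#' @param k_grid diffusion exponent search grid.
#' @param exact if `TRUE`, bypass sampling and use every voxel as a landmark
#'   (the dense filter; only sensible for small volumes).
#' @param sinkhorn_max_iter,sinkhorn_tol Sinkhorn stopping rule.
#' @return a `gmrid_denoise_result` with fields `volume` (denoised
#'   [as_volume()]), `k_hat`, `m_hat`, `mse_curve`, and `diagnostics`
#'   (Sinkhorn residual and iterations, spectrum summary, landmark count,
#'   seed, timing).
#' @export
denoise <- function(vol, noise, kernel = NULL,
                    scheme = c("kmeans", "uniform"), rate = 0.01,
                    rank = 100L, seed = 1L,
                    k_grid = c(0, seq(0.5, 8, by = 0.5)),
                    exact = FALSE,
                    sinkhorn_max_iter = 200L, sinkhorn_tol = 1e-6) {
  t0 <- proc.time()[["elapsed"]]
  vol <- as_volume(vol)
  stopifnot(inherits(noise, "gmrid_noise_model"))
  if (is.null(kernel)) kernel <- kernel_spec(1L, max(noise$sigma, 0.05))
  scheme <- match.arg(scheme)
  if (rate <= 0 || rate > 1) stop_contract("sampling rate must lie in (0, 1]")
  n <- n_voxels(vol)
  rank <- as.integer(rank)

  scaling <- rescale01(vol)
  y <- scaling$y
  sigma <- noise$sigma
  rician <- noise$family == "rician"
  ystab <- if (rician) vst_forward(y, sigma) else y

  if (exact) {
    l <- n
  } else {
    l <- ceiling(rate * n)
    if (l < rank) {
      warning(sprintf("sampling rate %.4g gives %d landmarks < rank %d; clamped to rank",
                      rate, l, rank))
      l <- rank
    }
    l <- min(l, n)
  }
  rank <- min(rank, l)

  work <- as_volume(array(ystab, dim = vol$shape), voxel_size = vol$voxel_size)
  samples <- if (exact || l == n) {
    sample_set(seq_len(n), scheme, seed)
  } else if (scheme == "kmeans") {
    kmeans_sample(work, l, spec = kernel, seed = seed)
  } else {
    uniform_sample(work, l, seed = seed)
  }

  blocks <- compute_kernel_blocks(work, samples, kernel)
  scaled <- sinkhorn_symmetrize(blocks, max_iter = sinkhorn_max_iter,
                                tol = sinkhorn_tol)
  spectrum <- orthogonalize_filter(scaled, m = rank)
  proj <- project(spectrum, ystab, sigma = sigma)
  sel <- select_diffusion(spectrum$eigvals, proj, sigma, k_grid = k_grid)
  xs <- apply_global_filter(spectrum, ystab, sel)
  if (rician) xs <- vst_inverse(xs, sigma)
  out <- restore01(xs, scaling)

  structure(list(
    volume = as_volume(array(out, dim = vol$shape),
                       voxel_size = vol$voxel_size),
    k_hat = sel$k, m_hat = sel$m,
    mse_curve = sel$curve,
    diagnostics = list(
      sinkhorn_residual = scaled$residual,
      sinkhorn_iterations = scaled$iterations,
      sinkhorn_converged = scaled$converged,
      eigvals = spectrum$eigvals,
      l = l, rank = rank, scheme = samples$scheme, seed = seed,
      noise = noise,
      elapsed_s = proc.time()[["elapsed"]] - t0)),
    class = "gmrid_denoise_result")
}

#' @export
print.gmrid_denoise_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(paste0("<gmrid_denoise_result> %s noise (sigma = %.4g), ",
                     "%s sampling, l = %d, rank = %d\n",
                     "  selected k = %.2g, m = %d; sinkhorn residual %.2e ",
                     "(%d iters); %.2f s\n"),
              d$noise$family, d$noise$sigma, d$scheme, d$l, d$rank,
              x$k_hat, x$m_hat, d$sinkhorn_residual,
              d$sinkhorn_iterations, d$elapsed_s))
  invisible(x)
}
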