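# Nystrom low-rank engine: eigen-approximation from sampled kernel columns,
# Sinkhorn doubly-stochastic scaling of the sampled representation, and the
# one-shot orthogonalization that yields the final filter spectrum.

# Symmetric eigendecomposition of M1 with a relative ridge: if the smallest
# retained eigenvalue falls below delta * max, a ridge delta * max * I is
# added before any inversion so the Nystrom extension stays stable.
m1_eigen <- function(M1, delta = 1e-10) {
  eg <- eigen(M1, symmetric = TRUE)
  lmax <- max(eg$values)
  if (lmax <= 0)
    stop_contract("landmark block is numerically indefinite (max eigenvalue %.3e)", lmax)
  if (min(eg$values) < -1e-8 * lmax)
    stop_contract("landmark block is numerically indefinite (min eigenvalue %.3e)",
                  min(eg$values))
  ridge <- 0
  if (min(eg$values) < delta * lmax) {
    ridge <- delta * lmax
    eg$values <- eg$values + ridge
    message(sprintf("nystrom: ridge %.3e added to landmark block", ridge))
  }
  eg
}

#' Nystrom eigen-approximation from sampled kernel columns
#'
#' Eigendecomposes the landmark block `M1 = G1 E1 G1'`, keeps the top `r`
#' eigenpairs, and extends the eigenvectors to all `n` voxels through the
#' sampled cross block: the extension rows are `M12' G1 E1^{-1}`. The
#' resulting factors approximate the leading eigenpairs of the full affinity
#' matrix without ever forming it.
#'
#' @param blocks a [compute_kernel_blocks()] result.
#' @param r retained rank, `1 <= r <= l`.
#' @return a `gmrid_nystrom_factors` object with `eigvecs` (`n x r`,
#'   sample-first row order), `eigvals` (descending), `l`, `r` and
#'   `sample_order`.
#' @export
nystrom_eigs <- function(blocks, r) {
  stopifnot(inherits(blocks, "gmrid_kernel_blocks"))
  r <- as.integer(r)
  if (r < 1L || r > blocks$l)
    stop_contract("need 1 <= r <= l = %d", blocks$l)
  eg <- m1_eigen(blocks$M1)
  keep <- seq_len(r)
  G1 <- eg$vectors[, keep, drop = FALSE]
  E1 <- eg$values[keep]
  ext <- crossprod(blocks$M12, G1) %*% diag(1 / E1, r)
  structure(list(eigvecs = rbind(G1, ext), eigvals = E1,
                 l = blocks$l, r = r, n = blocks$n,
                 sample_order = blocks$sample_order),
            class = "gmrid_nystrom_factors")
}

#' Dense Nystrom kernel reconstruction (test scale only)
#'
#' Materializes the approximated kernel `G E G'`. Intended for oracles and
#' accuracy scoring on small volumes; refuses to build matrices beyond
#' `dense_limit` rows.
#'
#' @param factors a [nystrom_eigs()] result.
#' @param reorder if `TRUE` (default) rows/columns are permuted back to
#'   canonical voxel order; otherwise landmarks come first.
#' @param dense_limit maximum `n` for which the dense matrix is built.
#' @return dense `n x n` matrix.
#' @export
reconstruct_kernel <- function(factors, reorder = TRUE, dense_limit = 5000L) {
  stopifnot(inherits(factors, "gmrid_nystrom_factors"))
  n <- factors$n
  if (n > dense_limit)
    stop_contract("refusing to materialize a %d x %d matrix (dense_limit = %d)",
                  n, n, dense_limit)
  K <- factors$eigvecs %*% (factors$eigvals * t(factors$eigvecs))
  if (reorder) {
    inv <- order(factors$sample_order)
    K <- K[inv, inv]
  }
  K
}

# Matrix-vector product with the Nystrom-reconstructed kernel, from blocks:
# M~ v = A M1^{-1} A' v with A = [M1; M12']. Never materializes M~.
nystrom_matvec_factory <- function(blocks, delta = 1e-10) {
  eg <- m1_eigen(blocks$M1, delta)
  Q <- eg$vectors
  inv_vals <- 1 / eg$values
  l <- blocks$l
  function(v) {
    vs <- v[seq_len(l)]
    vr <- v[-seq_len(l)]
    # A' v = M1 vs + M12 vr
    av <- drop(blocks$M1 %*% vs)
    if (length(vr)) av <- av + drop(blocks$M12 %*% vr)
    w <- drop(Q %*% (inv_vals * drop(crossprod(Q, av))))
    top <- drop(blocks$M1 %*% w)
    bottom <- if (length(vr)) drop(crossprod(blocks$M12, w)) else numeric(0)
    c(top, bottom)
  }
}

# One-shot orthogonalized eigensystem of the full (rank-l) Nystrom
# reconstruction B~ = A B1^{-1} A', A = [B1; B12']: with
# S = B1 + B1^{-1/2} B12 B12' B1^{-1/2} = U L U', the orthonormal
# eigenvectors of B~ are V = A B1^{-1/2} U L^{-1/2} with eigenvalues L.
# Truncating to the m leading columns gives the best rank-m approximation
# of B~ itself (not of the truncated landmark block), which is what both
# the filter spectrum and the accuracy scoring need.
one_shot_spectrum <- function(B1, B12, m, delta = 1e-10) {
  l <- nrow(B1)
  eg <- eigen(B1, symmetric = TRUE)
  lmax <- max(eg$values)
  if (lmax <= 0)
    stop_contract("landmark block is singular beyond repair (condition number infinite)")
  vals <- pmax(eg$values, delta * lmax)
  clipped <- min(eg$values) <= 0
  B1_mhalf <- eg$vectors %*% (1 / sqrt(vals) * t(eg$vectors))
  S <- B1
  if (ncol(B12) > 0) S <- S + tcrossprod(B1_mhalf %*% B12)
  S <- (S + t(S)) / 2
  egs <- eigen(S, symmetric = TRUE)
  pos <- egs$values > delta * max(egs$values, 0)
  if (!any(pos))
    stop_contract("orthogonalization produced no positive eigenvalues")
  keep <- which(pos)[seq_len(min(m, sum(pos)))]
  E <- egs$values[keep]
  U <- egs$vectors[, keep, drop = FALSE]
  B <- B1_mhalf %*% U %*% diag(1 / sqrt(E), length(E))
  V <- rbind(B1 %*% B, crossprod(B12, B))
  list(V = V, E = E, clipped = clipped, lmax = lmax,
       lmin = min(eg$values))
}

#' Sinkhorn scaling of the sampled kernel blocks
#'
#' Finds a positive diagonal scaling `d` such that `diag(d) M~ diag(d)` is
#' (approximately) doubly stochastic, where `M~` is the Nystrom
#' reconstruction implied by the blocks. The symmetric fixed-point iteration
#' `d <- sqrt(d / (M~ d))` only needs matrix-vector products with the
#' sampled representation; the scaling is then applied consistently to `M1`
#' and `M12`, which scales the implied reconstruction exactly. Inputs that
#' are already doubly stochastic are returned unchanged.
#'
#' @param blocks a [compute_kernel_blocks()] result.
#' @param max_iter maximum number of scaling sweeps.
#' @param tol convergence tolerance on `max | row_sum - 1 |` over all `n`
#'   approximated rows.
#' @return a `gmrid_scaled_blocks` object with the scaled `W1`, `W12`, the
#'   scaling vector `d` (sample-first order), the achieved `residual`, the
#'   iteration count and a `converged` flag. Non-convergence returns the
#'   best iterate with `converged = FALSE` and a warning, not an error.
#' @export
sinkhorn_symmetrize <- function(blocks, max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(blocks, "gmrid_kernel_blocks"))
  if (max_iter < 1L) stop_contract("max_iter must be >= 1")
  mv <- nystrom_matvec_factory(blocks)
  n <- blocks$n
  d <- rep(1, n)
  best <- list(d = d, residual = Inf)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    s <- mv(d)
    s <- pmax(s, .Machine$double.eps)
    resid <- max(abs(d * s - 1))
    if (resid < best$residual) best <- list(d = d, residual = resid)
    if (resid <= tol) { iters <- it - 1L; break }
    d <- sqrt(d / s)
    iters <- it
  }
  if (best$residual > tol) {
    s <- mv(d); s <- pmax(s, .Machine$double.eps)
    resid <- max(abs(d * s - 1))
    if (resid < best$residual) best <- list(d = d, residual = resid)
  }
  d <- best$d
  converged <- best$residual <= tol
  if (!converged)
    warning(sprintf("sinkhorn did not reach tol %.1e in %d iterations (residual %.3e)",
                    tol, max_iter, best$residual))
  l <- blocks$l
  ds <- d[seq_len(l)]
  dr <- d[-seq_len(l)]
  W1 <- blocks$M1 * tcrossprod(ds)
  W12 <- if (length(dr)) blocks$M12 * outer(ds, dr) else blocks$M12
  structure(list(W1 = W1, W12 = W12, d = d,
                 residual = best$residual, iterations = iters,
                 converged = converged,
                 sample_order = blocks$sample_order, l = l, n = n),
            class = "gmrid_scaled_blocks")
}

#' Orthogonalized filter spectrum
#'
#' Turns the Sinkhorn-scaled blocks into an orthonormal eigensystem of the
#' implied symmetric filter: with `O = W1 + W1^{-1/2} W12 W12' W1^{-1/2}`
#' eigendecomposed as `O = Vo Eo Vo'`, the filter eigenvectors are
#' `V = [W1; W12'] W1^{-1/2} Vo Eo^{-1/2}` and its eigenvalues are `Eo`.
#' `V' V = I` holds by construction. Eigenvalues marginally above 1 (an
#' artifact of the approximation; a doubly stochastic filter has spectrum in
#' `[0, 1]`) are clipped to 1, and directions with non-positive `Eo` are
#' dropped so the inverse square root is defined.
#'
#' @param W1 symmetric positive definite `l x l` scaled landmark block, or a
#'   `gmrid_scaled_blocks` object (then `W12` is taken from it).
#' @param W12 `l x (n - l)` scaled cross block.
#' @param m number of leading eigenpairs to keep, `m <= l`.
#' @param sample_order permutation placing landmarks first (required when
#'   passing raw matrices).
#' @param delta relative eigenvalue floor for the `W1^{-1/2}` square root.
#' @return a `gmrid_filter_spectrum` with `eigvecs` (`n x m`, sample-first
#'   order), `eigvals` (descending, in `[0, 1]`) and `sample_order`.
#' @export
orthogonalize_filter <- function(W1, W12 = NULL, m = NULL,
                                 sample_order = NULL, delta = 1e-10) {
  if (inherits(W1, "gmrid_scaled_blocks")) {
    sb <- W1
    W1 <- sb$W1; W12 <- sb$W12; sample_order <- sb$sample_order
  }
  W1 <- as.matrix(W1)
  l <- nrow(W1)
  W12 <- if (is.null(W12)) matrix(0, l, 0) else as.matrix(W12)
  if (is.null(m)) m <- l
  m <- as.integer(m)
  if (m < 1L || m > l) stop_contract("need 1 <= m <= l = %d", l)
  n <- l + ncol(W12)
  if (is.null(sample_order)) sample_order <- seq_len(n)
  if (max(abs(W1 - t(W1))) > 1e-8)
    stop_contract("W1 must be symmetric")

  os <- one_shot_spectrum(W1, W12, m, delta)
  if (os$clipped)
    message(sprintf("orthogonalize_filter: W1 eigenvalues clipped at %.3e (cond %.3e)",
                    delta * os$lmax,
                    os$lmax / max(os$lmin, delta * os$lmax)))
  structure(list(eigvecs = os$V,
                 eigvals = pmin(pmax(os$E, 0), 1),
                 raw_eigvals = os$E,
                 sample_order = sample_order,
                 l = l, n = n, m = length(os$E)),
            class = "gmrid_filter_spectrum")
}
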