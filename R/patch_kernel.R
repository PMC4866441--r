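#' Similarity kernel specification
#'
#' Parameters of the non-local-means style patch kernel
#' `K(p, q) = exp(-||p - q||^2 / (L h^2))`, where `L = (2r + 1)^3` is the
#' patch length. The per-element normalization makes the bandwidth `h`
#' comparable across patch radii; `h` is expressed on the rescaled `[0, 1]`
#' intensity range.
#'
#' @param patch_radius non-negative integer patch radius in voxels; the patch
#'   is the `(2r+1)^3` cube around each voxel, mirror-padded at the borders.
#' @param bandwidth_h positive kernel bandwidth on `[0, 1]` intensities.
#' @param kernel_family currently only `"nlm_gaussian"`; a registry point for
#'   alternative patch kernels.
#' @return a `gmrid_kernel_spec` object.
#' @export
kernel_spec <- function(patch_radius = 1L, bandwidth_h = 0.4,
                        kernel_family = "nlm_gaussian") {
  patch_radius <- as.integer(patch_radius)
  kernel_family <- match.arg(kernel_family)
  if (patch_radius < 0L) stop_contract("patch_radius must be >= 0")
  if (!is.numeric(bandwidth_h) || bandwidth_h <= 0)
    stop_contract("bandwidth_h must be > 0")
  structure(list(patch_radius = patch_radius,
                 bandwidth_h = as.numeric(bandwidth_h),
                 kernel_family = kernel_family,
                 patch_length = (2L * patch_radius + 1L)^3L),
            class = "gmrid_kernel_spec")
}

# Mirror-reflected coordinate: c < 1 reflects to 2 - c, c > n to 2n - c
# (no edge repetition). Applied iteratively so it is total for any radius.
reflect_coord <- function(x, n) {
  if (n == 1L) return(rep(1L, length(x)))
  repeat {
    bad_lo <- x < 1L
    bad_hi <- x > n
    if (!any(bad_lo | bad_hi)) return(x)
    x[bad_lo] <- 2L - x[bad_lo]
    x[bad_hi] <- 2L * n - x[bad_hi]
  }
}

# Mirror-pad a 3D array by r voxels on every side.
pad_mirror <- function(a, r) {
  if (r == 0L) return(a)
  d <- dim(a)
  ix <- reflect_coord(seq.int(1L - r, d[1L] + r), d[1L])
  iy <- reflect_coord(seq.int(1L - r, d[2L] + r), d[2L])
  iz <- reflect_coord(seq.int(1L - r, d[3L] + r), d[3L])
  a[ix, iy, iz, drop = FALSE]
}

# Fixed patch scan order: offsets with the first axis varying fastest,
# then the second, then the third (consistent with the linearization).
patch_offsets <- function(radius) {
  s <- seq.int(-radius, radius)
  as.matrix(expand.grid(dx = s, dy = s, dz = s, KEEP.OUT.ATTRS = FALSE))
}

#' Extract a 3D patch around a voxel
#'
#' Returns the `(2r+1)^3` neighborhood of a voxel as a vector in the fixed
#' scan order (first axis fastest). Neighbors falling outside the volume are
#' filled by mirror reflection about the boundary.
#'
#' @param vol a [as_volume()] object.
#' @param index linear voxel index in `[1, n]` (canonical linearization).
#' @param radius non-negative integer patch radius.
#' @return numeric vector of length `(2r+1)^3`.
#' @export
extract_patch <- function(vol, index, radius) {
  vol <- as_volume(vol)
  n <- n_voxels(vol)
  if (length(index) != 1L || index < 1L || index > n)
    stop_contract("voxel index must lie in [1, %d]", n)
  cc <- vol_coords(vol$shape, as.integer(index))
  off <- patch_offsets(as.integer(radius))
  ix <- reflect_coord(cc[1L] + off[, 1L], vol$shape[1L])
  iy <- reflect_coord(cc[2L] + off[, 2L], vol$shape[2L])
  iz <- reflect_coord(cc[3L] + off[, 3L], vol$shape[3L])
  vol$data[cbind(ix, iy, iz)]
}

# All-voxel patch matrix (n x L), built by shifting the mirror-padded array.
# Row i is extract_patch(vol, i, radius).
patch_matrix <- function(vol, radius) {
  vol <- as_volume(vol)
  r <- as.integer(radius)
  d <- vol$shape
  n <- prod(d)
  pa <- pad_mirror(vol$data, r)
  off <- patch_offsets(r)
  L <- nrow(off)
  P <- matrix(0, n, L)
  for (c in seq_len(L)) {
    P[, c] <- pa[seq.int(1L + r + off[c, 1L], length.out = d[1L]),
                 seq.int(1L + r + off[c, 2L], length.out = d[2L]),
                 seq.int(1L + r + off[c, 3L], length.out = d[3L])]
  }
  P
}

#' Patch similarity weight
#'
#' `exp(-||p - q||^2 / (L h^2))` with `L` the patch length: symmetric in its
#' arguments, equal to 1 iff the patches coincide, and strictly decreasing in
#' the Euclidean patch distance.
#'
#' @param p,q numeric patch vectors of equal length.
#' @param spec a [kernel_spec()].
#' @return similarity in `(0, 1]`.
#' @export
kernel_weight <- function(p, q, spec) {
  stopifnot(inherits(spec, "gmrid_kernel_spec"))
  if (length(p) != length(q))
    stop_contract("patch length mismatch: %d vs %d", length(p), length(q))
  exp(-sum((p - q)^2) / (length(p) * spec$bandwidth_h^2))
}

#' Sampled blocks of the global affinity matrix
#'
#' Computes the landmark rows of the patch-similarity matrix `M`: the
#' symmetric `l x l` block `M1` over landmark voxels and the `l x (n - l)`
#' block `M12` between landmarks and all remaining voxels. The full `n x n`
#' matrix is never materialized; `M12` is filled in streamed column chunks.
#'
#' @param vol a [as_volume()] object (intensities on any scale; callers that
#'   want a scale-free bandwidth should rescale to `[0, 1]` first, as
#'   [denoise()] does).
#' @param samples a [uniform_sample()] / [kmeans_sample()] landmark set.
#' @param spec a [kernel_spec()].
#' @param chunk_size number of non-landmark columns processed per block.
#' @return a `gmrid_kernel_blocks` object with fields `M1`, `M12`,
#'   `sample_order` (the permutation placing landmarks first), `l` and `n`.
#' @export
compute_kernel_blocks <- function(vol, samples, spec, chunk_size = 8192L) {
  vol <- as_volume(vol)
  stopifnot(inherits(spec, "gmrid_kernel_spec"))
  idx <- as.integer(samples$indices)
  n <- n_voxels(vol)
  l <- length(idx)
  if (l < 1L || l > n) stop_contract("need 1 <= l <= n landmarks")
  if (anyDuplicated(idx)) stop_contract("duplicate landmark indices")
  P <- patch_matrix(vol, spec$patch_radius)
  L <- ncol(P)
  h2L <- spec$bandwidth_h^2 * L
  Ps <- P[idx, , drop = FALSE]
  sq_s <- rowSums(Ps^2)

  d1 <- outer(sq_s, sq_s, "+") - 2 * tcrossprod(Ps)
  M1 <- exp(-pmax(d1, 0) / h2L)
  M1 <- (M1 + t(M1)) / 2
  diag(M1) <- 1

  rest <- setdiff(seq_len(n), idx)
  M12 <- matrix(0, l, length(rest))
  if (length(rest)) {
    sq_all <- rowSums(P^2)
    starts <- seq.int(1L, length(rest), by = chunk_size)
    for (s in starts) {
      cols <- rest[seq.int(s, min(s + chunk_size - 1L, length(rest)))]
      d <- outer(sq_s, sq_all[cols], "+") - 2 * Ps %*% t(P[cols, , drop = FALSE])
      M12[, seq.int(s, length.out = length(cols))] <- exp(-pmax(d, 0) / h2L)
    }
  }
  kernel_blocks(M1, M12, sample_order = c(idx, rest))
}

#' Low-level kernel block constructor
#'
#' Assembles a `gmrid_kernel_blocks` object from explicit matrices; used by
#' [compute_kernel_blocks()] and by callers that build blocks for synthetic
#' positive semidefinite kernels.
#'
#' @param M1 symmetric `l x l` landmark block.
#' @param M12 `l x (n - l)` landmarks-vs-rest block (0 columns allowed).
#' @param sample_order length-`n` permutation placing landmarks first.
#' @return a `gmrid_kernel_blocks` object.
#' @export
kernel_blocks <- function(M1, M12, sample_order) {
  M1 <- as.matrix(M1); M12 <- as.matrix(M12)
  l <- nrow(M1)
  if (ncol(M1) != l) stop_contract("M1 must be square")
  if (max(abs(M1 - t(M1))) > 1e-10)
    stop_contract("M1 must be symmetric")
  if (nrow(M12) != l) stop_contract("M12 must have l rows")
  n <- l + ncol(M12)
  sample_order <- as.integer(sample_order)
  if (length(sample_order) != n || anyDuplicated(sample_order))
    stop_contract("sample_order must be a permutation of 1..n")
  structure(list(M1 = M1, M12 = M12, sample_order = sample_order,
                 l = l, n = n),
            class = "gmrid_kernel_blocks")
}
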