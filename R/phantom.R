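#' Synthetic multi-tissue 3D phantom
#'
#' Generates a piecewise-constant ground-truth volume emulating a
#' multi-tissue MR acquisition at desk scale: an ellipsoidal "head" region
#' on an exact-zero background (background occupies the majority of voxels,
#' which is what makes adaptive landmark sampling worthwhile), partitioned
#' into tissues by thresholding a smooth random field so region boundaries
#' are smooth but intensities within a tissue are exactly constant.
#'
#' @param shape integer length-3 volume shape, each axis `>= 8`.
#' @param n_tissues number of tissue classes, `>= 2`.
#' @param smoothness highest spatial frequency (cycles per volume extent) of
#'   the random field shaping the tissue regions; smaller values give
#'   blobbier, smoother regions.
#' @param seed integer seed; phantoms are deterministic per seed.
#' @return a `gmrid_phantom` with `truth` (a [as_volume()]), `labels`
#'   (0 = background), `tissue_means` and `seed`.
#' @export
generate_phantom <- function(shape = c(16L, 16L, 16L), n_tissues = 3L,
                             smoothness = 3, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop_contract("shape must have 3 axes, each >= 8")
  n_tissues <- as.integer(n_tissues)
  if (n_tissues < 2L) stop_contract("need n_tissues >= 2")

  cx <- (shape + 1) / 2
  semi <- 0.38 * shape
  u <- (slice.index(array(0, shape), 1) - cx[1]) / semi[1]
  v <- (slice.index(array(0, shape), 2) - cx[2]) / semi[2]
  w <- (slice.index(array(0, shape), 3) - cx[3]) / semi[3]
  mask <- (u^2 + v^2 + w^2) <= 1

  field <- with_seed(seed, {
    gx <- slice.index(array(0, shape), 1) / shape[1]
    gy <- slice.index(array(0, shape), 2) / shape[2]
    gz <- slice.index(array(0, shape), 3) / shape[3]
    f <- array(0, shape)
    for (j in seq_len(8L)) {
      fr <- runif(3, -smoothness, smoothness)
      ph <- runif(1, 0, 2 * pi)
      f <- f + rnorm(1) * cos(2 * pi * (fr[1] * gx + fr[2] * gy + fr[3] * gz) + ph)
    }
    f
  })

  labels <- array(0L, shape)
  inside <- field[mask]
  qs <- stats::quantile(inside, probs = seq(0, 1, length.out = n_tissues + 1L))
  qs[1] <- -Inf; qs[n_tissues + 1L] <- Inf
  labels[mask] <- as.integer(cut(inside, breaks = unique(qs),
                                 include.lowest = TRUE))
  # degenerate fields (ties) can drop classes; spread by rank if so
  if (length(unique(labels[mask])) < n_tissues) {
    rk <- rank(inside, ties.method = "first")
    labels[mask] <- as.integer(ceiling(rk / length(inside) * n_tissues))
  }
  means <- seq(0.35, 1, length.out = n_tissues)
  truth <- array(0, shape)
  truth[mask] <- means[labels[mask]]
  structure(list(truth = as_volume(truth), labels = labels,
                 tissue_means = means, seed = as.integer(seed)),
            class = "gmrid_phantom")
}

#' Add synthetic noise to a volume
#'
#' Noise levels follow the common MRI convention of a percentage of the
#' maximum intensity: `sigma = sigma_pct / 100 * max(vol)`. Gaussian noise
#' is additive; Rician noise is the magnitude of the complex Gaussian
#' perturbation, `sqrt((x + n1)^2 + n2^2)` with `n1, n2` iid
#' `N(0, sigma^2)`, and requires nonnegative input.
#'
#' @param vol a [as_volume()] object (or 3D array).
#' @param sigma_pct noise standard deviation as percent of the maximum
#'   intensity, `>= 0`.
#' @param seed integer seed; deterministic per seed.
#' @return a noisy [as_volume()] object.
#' @export
add_gaussian_noise <- function(vol, sigma_pct, seed = 1L) {
  vol <- as_volume(vol)
  if (sigma_pct < 0) stop_contract("sigma_pct must be >= 0")
  if (sigma_pct == 0) return(vol)
  sigma <- sigma_pct / 100 * max(vol$data)
  noisy <- with_seed(seed, vol$data + array(rnorm(n_voxels(vol), sd = sigma),
                                            dim = vol$shape))
  as_volume(noisy, voxel_size = vol$voxel_size)
}

#' @rdname add_gaussian_noise
#' @export
add_rician_noise <- function(vol, sigma_pct, seed = 1L) {
  vol <- as_volume(vol)
  if (any(vol$data < 0))
    stop_contract("Rician noise requires nonnegative intensities")
  if (sigma_pct < 0) stop_contract("sigma_pct must be >= 0")
  if (sigma_pct == 0) return(vol)
  sigma <- sigma_pct / 100 * max(vol$data)
  n <- n_voxels(vol)
  noisy <- with_seed(seed, {
    n1 <- array(rnorm(n, sd = sigma), dim = vol$shape)
    n2 <- array(rnorm(n, sd = sigma), dim = vol$shape)
    sqrt((vol$data + n1)^2 + n2^2)
  })
  as_volume(noisy, voxel_size = vol$voxel_size)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in decibels; identical volumes return the capped
#' value 999.
#'
#' @param ref,test volumes (or 3D arrays) of identical shape.
#' @param peak dynamic range; defaults to the intensity range of `ref`.
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, peak = NULL) {
  ref <- as_volume(ref); test <- as_volume(test)
  if (!all(ref$shape == test$shape))
    stop_contract("shape mismatch: %s vs %s",
                  paste(ref$shape, collapse = "x"),
                  paste(test$shape, collapse = "x"))
  if (is.null(peak)) peak <- diff(ref$intensity_range)
  if (peak <= 0) stop_contract("peak must be > 0")
  mse <- mean((ref$data - test$data)^2)
  if (mse == 0) return(999)
  min(10 * log10(peak^2 / mse), 999)
}

# 1D Gaussian window, normalized
gaussian_window <- function(size = 7L, sd = 1.5) {
  x <- seq.int(-(size %/% 2L), size %/% 2L)
  g <- exp(-x^2 / (2 * sd^2))
  g / sum(g)
}

# smoothing matrix along one axis with mirror boundary handling
smooth_matrix <- function(n, g) {
  r <- (length(g) - 1L) %/% 2L
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- reflect_coord(seq.int(i - r, i + r), n)
    for (t in seq_along(g)) S[i, js[t]] <- S[i, js[t]] + g[t]
  }
  S
}

# separable Gaussian smoothing of a 3D array
smooth3d <- function(a, g) {
  d <- dim(a)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- smooth_matrix(dp[1L], g) %*% matrix(ap, dp[1L])
    a <- aperm(array(m, dp), order(perm))
  }
  a
}

#' Structural similarity index (3D)
#'
#' Mean local SSIM over the volume with the standard constants
#' `K1 = 0.01`, `K2 = 0.03`, a 7x7x7 Gaussian window (sd 1.5 voxels, mirror
#' boundary) and dynamic range `peak`. Symmetric in its arguments.
#'
#' @param ref,test volumes (or 3D arrays) of identical shape.
#' @param peak dynamic range; defaults to the joint intensity range of both
#'   volumes (keeping the score symmetric).
#' @return score in `[-1, 1]`.
#' @export
ssim <- function(ref, test, peak = NULL) {
  ref <- as_volume(ref); test <- as_volume(test)
  if (!all(ref$shape == test$shape))
    stop_contract("shape mismatch: %s vs %s",
                  paste(ref$shape, collapse = "x"),
                  paste(test$shape, collapse = "x"))
  if (is.null(peak))
    peak <- diff(range(c(ref$intensity_range, test$intensity_range)))
  if (peak <= 0) peak <- 1
  C1 <- (0.01 * peak)^2
  C2 <- (0.03 * peak)^2
  g <- gaussian_window()
  x <- ref$data; y <- test$data
  mx <- smooth3d(x, g); my <- smooth3d(y, g)
  sxx <- smooth3d(x * x, g) - mx^2
  syy <- smooth3d(y * y, g) - my^2
  sxy <- smooth3d(x * y, g) - mx * my
  s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(s)
}
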