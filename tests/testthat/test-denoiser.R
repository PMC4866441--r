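make_spectrum <- function(vol, l = 60L, m = 40L, seed = 1) {
  samp <- uniform_sample(vol, l, seed = seed)
  blocks <- compute_kernel_blocks(vol, samp, kernel_spec(1, 0.4))
  sk <- sinkhorn_symmetrize(blocks, max_iter = 500L, tol = 1e-9)
  orthogonalize_filter(sk, m = m)
}

test_that("projection respects orthonormality and shrinkage contracts", {
  v <- rand_volume(c(5, 5, 5), seed = 3)
  spec <- make_spectrum(v)
  n <- n_voxels(v)

  # y equal to an eigenvector projects onto a single coefficient
  y1 <- numeric(n); y1[spec$sample_order] <- spec$eigvecs[, 1]
  p1 <- project(spec, y1)
  expect_equal(p1$coeffs[1], 1, tolerance = 1e-8)
  expect_lt(max(abs(p1$coeffs[-1])), 1e-8)

  # zero input: all coefficients zero
  p0 <- project(spec, numeric(n))
  expect_true(all(p0$coeffs == 0) && all(p0$shrunk_b2 == 0))

  # sigma = 0: no shrinkage
  set.seed(2); y <- runif(n)
  p <- project(spec, y, sigma = 0)
  expect_identical(p$shrunk_b2, p$coeffs^2)
  # positive sigma subtracts and truncates at zero
  ps <- project(spec, y, sigma = 0.5)
  expect_equal(ps$shrunk_b2, pmax(p$coeffs^2 - 0.25, 0))

  expect_error(project(spec, y[-1]), "match")
})

test_that("risk proxy evaluates the closed forms", {
  pr <- structure(list(coeffs = 2, shrunk_b2 = 4), class = "gmrid_projection")
  expect_equal(estimate_mse_proxy(1, pr, 1, list(k = 1, m = 1)), -3)
  pr2 <- structure(list(coeffs = 1, shrunk_b2 = 1), class = "gmrid_projection")
  expect_equal(estimate_mse_proxy(0.5, pr2, 0, list(k = 2, m = 1)),
               0.5^4 - 2 * 0.5^2)
  # at sigma = 0 every term is <= 0, so the proxy is non-increasing in m
  set.seed(5)
  for (rep in 1:10) {
    lam <- sort(runif(12), decreasing = TRUE)
    prr <- structure(list(shrunk_b2 = runif(12)), class = "gmrid_projection")
    vals <- sapply(1:12, function(m)
      estimate_mse_proxy(lam, prr, 0, list(k = 1.5, m = m)))
    expect_true(all(diff(vals) <= 1e-14))
  }
  expect_error(estimate_mse_proxy(1, pr, -1, list(k = 1, m = 1)), "sigma")
  expect_error(estimate_mse_proxy(1, pr, 1, list(k = 1, m = 2)), "m must")
})

test_that("selection equals brute-force grid minimization", {
  brute <- function(eigvals, proj, sigma, k_grid, m_grid) {
    best <- NULL
    for (k in sort(k_grid)) for (m in sort(m_grid)) {
      val <- estimate_mse_proxy(eigvals, proj, sigma, list(k = k, m = m))
      if (is.null(best) || val < best$value)
        best <- list(k = k, m = m, value = val)
    }
    best
  }
  set.seed(11)
  for (rep in 1:100) {
    mlen <- sample(3:15, 1)
    lam <- c(1, sort(runif(mlen - 1), decreasing = TRUE))
    proj <- structure(list(shrunk_b2 = runif(mlen, 0, 4)),
                      class = "gmrid_projection")
    sigma <- runif(1, 0, 1.5)
    k_grid <- sort(sample(seq(0, 8, 0.5), 5))
    got <- select_diffusion(lam, proj, sigma, k_grid)
    want <- brute(lam, proj, sigma, k_grid, seq_len(mlen))
    expect_equal(got$value, want$value)
    expect_equal(c(got$k, got$m), c(want$k, want$m))
  }
  # sigma = 0 collapses to weakest smoothing and full rank
  lam <- c(1, 0.9, 0.5, 0.2)
  proj <- structure(list(shrunk_b2 = c(2, 1, 0.5, 0.2)),
                    class = "gmrid_projection")
  s0 <- select_diffusion(lam, proj, 0, k_grid = c(0.5, 1, 3))
  expect_equal(c(s0$k, s0$m), c(0.5, 4))
  # single pure-noise mode: the variance term favors stronger diffusion
  pn <- structure(list(shrunk_b2 = 0), class = "gmrid_projection")
  s1 <- select_diffusion(0.5, pn, 1, k_grid = c(1, 2), m_grid = 1L)
  expect_equal(s1$k, 2)
  expect_error(select_diffusion(lam, proj, 0, k_grid = numeric(0)), "nonempty")
})

test_that("the spectral filter is linear and matches dense matrix powers", {
  v <- rand_volume(c(5, 5, 5), seed = 13)
  n <- n_voxels(v)
  blocks <- compute_kernel_blocks(v, uniform_sample(v, n, 1), kernel_spec(1, 0.4))
  sk <- sinkhorn_symmetrize(blocks, max_iter = 1000L, tol = 1e-11)
  spec <- orthogonalize_filter(sk, m = n)

  # dense W from the scaled blocks, in voxel order
  inv <- order(blocks$sample_order)
  W <- sk$W1[inv, inv]
  set.seed(1); y <- runif(n)

  # integer powers: V E^k V' y = W^k y
  Wk <- W
  for (k in 1:3) {
    got <- apply_global_filter(spec, y, list(k = k, m = n))
    expect_lt(max(abs(got - drop(Wk %*% y))), 1e-6)
    Wk <- Wk %*% W
  }

  # linearity
  y2 <- rnorm(n)
  lhs <- apply_global_filter(spec, 2 * y - 3 * y2, list(k = 2, m = 20L))
  rhs <- 2 * apply_global_filter(spec, y, list(k = 2, m = 20L)) -
    3 * apply_global_filter(spec, y2, list(k = 2, m = 20L))
  expect_lt(max(abs(lhs - rhs)), 1e-10)

  # large k: matches the dense k = 50 power (oracle) and collapses toward
  # the projection onto the leading (DC-like) mode
  got50 <- apply_global_filter(spec, y, list(k = 50, m = n))
  expect_lt(max(abs(got50 - oracle_filter(W, y, 50))), 1e-6)
  v1 <- numeric(n); v1[blocks$sample_order] <- spec$eigvecs[, 1]
  lead <- sum(v1 * y) * v1
  got2 <- apply_global_filter(spec, y, list(k = 2, m = n))
  expect_lt(sqrt(sum((got50 - lead)^2)), 0.05 * sqrt(sum((got2 - lead)^2)))

  expect_error(apply_global_filter(spec, y, list(k = 1, m = n + 1L)), "m must")
})

test_that("denoising reduces variance on constant volumes and is deterministic", {
  base <- as_volume(array(0.5, c(10, 10, 10)))
  nm <- noise_model("gaussian", 0.05)
  worse <- 0L
  for (seed in 1:5) {
    noisy <- add_gaussian_noise(base, 10, seed = seed)
    res <- suppressWarnings(denoise(noisy, nm, rank = 30L, rate = 0.05,
                                    seed = seed))
    if (var(as.vector(res$volume$data)) >= var(as.vector(noisy$data)))
      worse <- worse + 1L
    expect_true(all(is.finite(res$volume$data)))
  }
  expect_equal(worse, 0L)

  noisy <- add_gaussian_noise(base, 10, seed = 9)
  r1 <- suppressWarnings(denoise(noisy, nm, rank = 30L, rate = 0.05, seed = 4))
  r2 <- suppressWarnings(denoise(noisy, nm, rank = 30L, rate = 0.05, seed = 4))
  expect_identical(r1$volume$data, r2$volume$data)
  expect_identical(c(r1$k_hat, r1$m_hat), c(r2$k_hat, r2$m_hat))
  # the reported optimum is the minimum of the reported curve
  expect_equal(min(r1$mse_curve$value),
               r1$mse_curve$value[r1$mse_curve$k == r1$k_hat &
                                  r1$mse_curve$m == r1$m_hat])
})

test_that("near-zero noise leaves a clean phantom essentially untouched", {
  ph <- generate_phantom(c(10, 10, 10), 3, seed = 2)
  res <- suppressMessages(denoise(ph$truth, noise_model("gaussian", 1e-6),
                                  exact = TRUE, rank = 1000L, seed = 1))
  expect_lt(max(abs(res$volume$data - ph$truth$data)), 1e-3)
})

test_that("denoise contract violations are caught", {
  v <- rand_volume(c(8, 8, 8), seed = 1)
  expect_error(denoise(v, noise_model("gaussian", 0.1), rate = 0), "rate")
  expect_error(noise_model("gaussian", -1), "positive")
  expect_warning(denoise(v, noise_model("gaussian", 0.1), rate = 1e-4,
                         rank = 40L, seed = 1),
                 "clamped")
})
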