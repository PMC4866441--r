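test_that("phantoms are deterministic, piecewise constant, mostly background", {
  ph <- generate_phantom(seed = 3)
  ph2 <- generate_phantom(seed = 3)
  expect_identical(ph$truth$data, ph2$truth$data)
  expect_identical(ph$labels, ph2$labels)

  # exactly n_tissues distinct nonbackground intensities
  ph_2t <- generate_phantom(n_tissues = 2L, seed = 5)
  nonbg <- ph_2t$truth$data[ph_2t$truth$data > 0]
  expect_length(unique(nonbg), 2L)

  # background fraction within the stated band for defaults, across seeds
  for (seed in 1:5) {
    p <- generate_phantom(seed = seed)
    bg <- mean(p$labels == 0L)
    expect_gte(bg, 0.5); expect_lte(bg, 0.9)
  }
  # labels congruent with intensities via the tissue means
  p <- generate_phantom(seed = 9)
  expect_equal(p$truth$data[p$labels > 0],
               p$tissue_means[p$labels[p$labels > 0]])

  expect_error(generate_phantom(c(4, 16, 16)), "shape")
  expect_error(generate_phantom(n_tissues = 1L), "n_tissues")
})

test_that("gaussian noise has the stated moments", {
  ph <- generate_phantom(c(32, 32, 32), seed = 1)
  expect_identical(add_gaussian_noise(ph$truth, 0, 1)$data, ph$truth$data)
  noisy <- add_gaussian_noise(ph$truth, 10, seed = 2)
  resid <- as.vector(noisy$data - ph$truth$data)
  sigma <- 0.1 * max(ph$truth$data)
  expect_lt(abs(var(resid) - sigma^2) / sigma^2, 0.05)
  expect_lt(abs(mean(resid)), 3 * sigma / sqrt(length(resid)))
  expect_identical(add_gaussian_noise(ph$truth, 10, seed = 2)$data, noisy$data)
})

test_that("rician noise is nonnegative with the Rayleigh background mean", {
  ph <- generate_phantom(c(52, 52, 52), seed = 2)   # >= 1e5 background voxels
  expect_identical(add_rician_noise(ph$truth, 0, 1)$data, ph$truth$data)
  noisy <- add_rician_noise(ph$truth, 15, seed = 3)
  expect_true(all(noisy$data >= 0))
  sigma <- 0.15 * max(ph$truth$data)
  bg <- noisy$data[ph$labels == 0L]
  expect_gt(length(bg), 1e5)
  expect_lt(abs(mean(bg) - sigma * sqrt(pi / 2)) / (sigma * sqrt(pi / 2)), 0.02)
  expect_error(add_rician_noise(as_volume(array(-1, c(8, 8, 8))), 5), "nonnegative")
})

test_that("PSNR matches closed forms and an independent computation", {
  v <- rand_volume(c(6, 6, 6), seed = 4)
  expect_equal(psnr(v, v), 999)
  # constant offset 0.1 at peak 1: 10 log10(1 / 0.01) = 20 dB
  shifted <- as_volume(v$data + 0.1)
  expect_equal(psnr(v, shifted, peak = 1), 20, tolerance = 1e-12)
  # random pair vs hand-coded MSE/log
  w <- rand_volume(c(6, 6, 6), seed = 5)
  hand <- 10 * log10(1 / mean((v$data - w$data)^2))
  expect_equal(psnr(v, w, peak = 1), hand, tolerance = 1e-12)
  expect_error(psnr(v, rand_volume(c(5, 6, 6))), "shape")
})

test_that("SSIM satisfies identity, symmetry and anti-correlation checks", {
  ph <- generate_phantom(c(16, 16, 16), 2L, seed = 6)
  x <- ph$truth
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)

  y <- add_gaussian_noise(x, 20, seed = 1)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_lt(ssim(x, y), 1)

  # inverted high-contrast phantom: structurally anti-correlated
  inv <- as_volume(max(x$data) - x$data)
  expect_lt(ssim(x, inv, peak = 1), 0.2)
})

test_that("SSIM agrees with a direct sliding-window reference", {
  # naive reference: explicit local moments over full 7^3 windows with the
  # same Gaussian weights, mirror-padded
  naive_ssim <- function(a, b, peak) {
    g1 <- exp(-(-3:3)^2 / (2 * 1.5^2)); g1 <- g1 / sum(g1)
    w3 <- outer(outer(g1, g1), g1)
    d <- dim(a)
    pa <- gmrid:::pad_mirror(a, 3L); pb <- gmrid:::pad_mirror(b, 3L)
    C1 <- (0.01 * peak)^2; C2 <- (0.03 * peak)^2
    tot <- 0
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      wa <- pa[i:(i + 6), j:(j + 6), k:(k + 6)]
      wb <- pb[i:(i + 6), j:(j + 6), k:(k + 6)]
      mx <- sum(w3 * wa); my <- sum(w3 * wb)
      vx <- sum(w3 * wa^2) - mx^2; vy <- sum(w3 * wb^2) - my^2
      cxy <- sum(w3 * wa * wb) - mx * my
      tot <- tot + ((2 * mx * my + C1) * (2 * cxy + C2)) /
        ((mx^2 + my^2 + C1) * (vx + vy + C2))
    }
    tot / prod(d)
  }
  set.seed(10)
  for (rep in 1:3) {
    a <- array(runif(9^3), c(9, 9, 9))
    b <- a + array(rnorm(9^3, sd = 0.1), c(9, 9, 9))
    expect_equal(ssim(as_volume(a), as_volume(b), peak = 1),
                 naive_ssim(a, b, 1), tolerance = 1e-6)
  }
})
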