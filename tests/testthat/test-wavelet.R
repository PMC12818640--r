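test_that("decomposition of a constant signal puts everything in the approximation", {
  dec <- dwt_decompose(rep(3.25, 256), wavelet_spec(j = 4))
  expect_lt(max(abs(unlist(dec$details))), 1e-12)
})

test_that("unmodified coefficients reconstruct the signal exactly", {
  set.seed(11)
  for (n in c(64, 300, 1800, 1807)) {
    x <- rnorm(n)
    for (fam in c("haar", "db2", "db4")) {
      dec <- dwt_decompose(x, wavelet_spec(family = fam, j = 4))
      expect_equal(dwt_reconstruct(dec), x, tolerance = 1e-10)
    }
  }
})

test_that("the transform is orthogonal (Parseval) on dyadic lengths", {
  set.seed(12)
  x <- rnorm(512)
  x[100] <- 25 # include an impulse
  dec <- dwt_decompose(x, wavelet_spec(j = 5))
  coef_energy <- sum(dec$approx^2) + sum(unlist(dec$details)^2)
  expect_equal(coef_energy, sum(x^2), tolerance = 1e-10)
})

test_that("decomposition rejects signals shorter than 2^J", {
  expect_error(dwt_decompose(rnorm(10), wavelet_spec(j = 4)),
               class = "rppg_input_error")
})

test_that("universal threshold follows the closed form", {
  # zero details -> zero threshold (denoising becomes a no-op)
  th0 <- universal_threshold(numeric(16), n = 1024)
  expect_equal(th0$threshold, 0)
  expect_equal(th0$sigma_hat, 0)
  # MAD of a known vector: direct evaluation of T = sigma * sqrt(2 log n)
  d <- c(-2, -1, 0, 1, 2) * 0.6745
  sigma <- stats::mad(d, constant = 1 / 0.6745)
  th <- universal_threshold(d, n = 1024)
  expect_equal(th$sigma_hat, sigma)
  expect_equal(th$threshold, sigma * sqrt(2 * log(1024)))
  # scale equivariance of the MAD-based estimate
  th10 <- universal_threshold(10 * d, n = 1024)
  expect_equal(th10$threshold, 10 * th$threshold)
})

test_that("soft thresholding matches the piecewise rule", {
  expect_equal(soft_threshold(0, 2), 0)
  expect_equal(soft_threshold(5, 2), 3)
  expect_equal(soft_threshold(-5, 2), -3)
  expect_equal(soft_threshold(1.5, 2), 0)
  set.seed(13)
  d <- rnorm(200, sd = 3)
  for (t in c(0, 0.5, 2, 10)) {
    expect_equal(soft_threshold(d, t), soft_threshold_oracle(d, t))
  }
  expect_error(soft_threshold(d, -1), class = "rppg_config_error")
})

test_that("denoising leaves a clean sinusoid essentially untouched", {
  x <- sin(2 * pi * 1.2 * (0:899) / 30)
  den <- dwt_denoise(x, wavelet_spec(j = 4), fps = 30)
  expect_equal(length(den$values), length(x))
  expect_gt(cor(den$values, x), 0.999)
})

test_that("denoising reduces the error of a noisy sinusoid and the variance of pure noise", {
  clean <- sin(2 * pi * 1.2 * (0:899) / 30)
  wins <- 0
  for (seed in 1:100) {
    set.seed(seed)
    noisy <- clean + rnorm(900, sd = 0.5)
    den <- dwt_denoise(noisy, wavelet_spec(j = 4))
    if (mean((den$values - clean)^2) < mean((noisy - clean)^2)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 95)
  set.seed(14)
  noise <- rnorm(1024)
  expect_lt(var(dwt_denoise(noise, wavelet_spec(j = 4))$values), var(noise))
})

test_that("denoising is scale-equivariant and only removes energy", {
  set.seed(15)
  x <- sin(2 * pi * 1.1 * (0:599) / 30) + rnorm(600, sd = 0.4)
  d1 <- dwt_denoise(x, wavelet_spec(j = 4))
  d7 <- dwt_denoise(7 * x, wavelet_spec(j = 4))
  expect_equal(d7$values, 7 * d1$values, tolerance = 1e-10)
  expect_lte(sum(d1$values^2), sum(x^2))
})

test_that("default level tracks the sampling rate and keeps the pulse in the approximation", {
  expect_equal(default_wavelet_level(30), 3L)
  expect_equal(default_wavelet_level(60), 4L)
  expect_equal(default_wavelet_level(500), 6L) # clamped
  j <- default_wavelet_level(30)
  approx_top <- 30 / 2^(j + 1)
  expect_gte(approx_top, 1.8)
})
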