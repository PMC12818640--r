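test_that("prediction follows the random-walk model", {
  cfg <- rakf_config(r0 = 25, q = 2e-4)
  pred <- rakf_predict(70, 25, cfg)
  expect_equal(pred$x_prior, 70)
  expect_equal(pred$p_prior, 25.0002)
  cfg0 <- rakf_config(q = 1e-12) # effectively zero process noise
  expect_equal(rakf_predict(70, 25, cfg0)$p_prior, 25)
  # repeated prediction grows the covariance linearly
  p <- 25
  for (i in 1:10) p <- rakf_predict(70, p, cfg)$p_prior
  expect_equal(p, 25 + 10 * 2e-4)
})

test_that("adaptive measurement noise follows R0 (1 + |residual|/beta)", {
  cfg <- rakf_config(r0 = 25, beta = 10)
  expect_equal(rakf_adaptive_r(0, cfg), 25)
  expect_equal(rakf_adaptive_r(10, cfg), 50)
  expect_equal(rakf_adaptive_r(-10, cfg), 50)
  set.seed(41)
  res <- sort(abs(rnorm(50, sd = 20)))
  r <- vapply(res, rakf_adaptive_r, numeric(1), config = cfg)
  expect_true(all(diff(r) >= 0))      # monotone in |residual|
  expect_true(all(r >= 25))
  expect_equal(r, 25 * (1 + res / 10))
  # beta = Inf disables adaptation
  expect_equal(rakf_adaptive_r(50, rakf_config(beta = Inf)), 25)
})

test_that("gain is P/(P+R) and shrinks as R inflates", {
  expect_equal(rakf_gain(25, 25), 0.5)
  expect_lt(rakf_gain(1e-9, 25), 1e-9)
  cfg <- rakf_config(r0 = 25, beta = 10)
  residuals <- seq(0, 50, 5)
  gains <- vapply(residuals, function(res) {
    rakf_gain(25, rakf_adaptive_r(res, cfg))
  }, numeric(1))
  expect_true(all(diff(gains) < 0)) # larger residual -> smaller gain
  expect_lte(rakf_gain(25, rakf_adaptive_r(5, cfg)), rakf_gain(25, 25))
})

test_that("outlier correction replaces gross deviations by the rolling median", {
  cfg <- rakf_config()
  hist <- c(70, 71, 72, 71, 70)
  ok <- rakf_correct_outlier(71, hist, config = cfg)
  expect_false(ok$replaced)
  expect_equal(ok$z_used, 71)
  bad <- rakf_correct_outlier(140, hist, config = cfg)
  expect_true(bad$replaced)
  expect_equal(bad$z_used, median(hist))
  none <- rakf_correct_outlier(140, numeric(0), config = cfg)
  expect_false(none$replaced)
  expect_equal(none$z_used, 140)
})

test_that("update applies the weight to the state but not the covariance", {
  cfg <- rakf_config(r0 = 25, q = 2e-4, beta = 10)
  # hand evaluation: x_prior 75, P_prior 25.0002, z 80 ->
  # residual 5, R = 25 * 1.5 = 37.5, K = 25.0002/62.5002
  upd <- rakf_update(75, 25.0002, 80, w = 1, cfg)
  k_expected <- 25.0002 / (25.0002 + 37.5)
  expect_equal(upd$residual, 5)
  expect_equal(upd$r_adaptive, 37.5)
  expect_equal(upd$gain, k_expected)
  expect_equal(upd$x, 75 + k_expected * 5)
  expect_equal(upd$p, (1 - k_expected) * 25.0002)
  # with weight w the state moves w times as far; covariance is unchanged
  upd_w <- rakf_update(75, 25.0002, 80, w = 0.4, cfg)
  expect_equal(upd_w$x - 75, 0.4 * (upd$x - 75))
  expect_equal(upd_w$p, upd$p)
})

test_that("with weighting, adaptation and outliers off the filter equals a textbook Kalman filter", {
  set.seed(42)
  z <- 72 + rnorm(1000, sd = 5)
  cfg <- rakf_config(r0 = 25, q = 0.72, beta = Inf, outlier = FALSE,
                     weighted = FALSE)
  fit <- rakf_filter(z, sq = 1, cfg)
  ref <- standard_kalman <- local({
    # independent textbook scalar filter
    x0 <- median(z[1:15])
    x <- numeric(1000)
    p <- numeric(1000)
    xc <- x0
    pc <- 25
    for (i in seq_along(z)) {
      pp <- pc + 0.72
      k <- pp / (pp + 25)
      xc <- xc + k * (z[i] - xc)
      pc <- (1 - k) * pp
      x[i] <- xc
      p[i] <- pc
    }
    list(x = x, p = p)
  })
  s <- tidy(fit)
  expect_equal(s$x_hat, ref$x, tolerance = 1e-10)
  expect_equal(s$p, ref$p, tolerance = 1e-10)
})

test_that("covariance contracts at every update and stays positive", {
  set.seed(43)
  z <- 70 + rnorm(200, sd = 8)
  fit <- rakf_filter(z, sq = runif(200), rakf_config())
  s <- tidy(fit)
  expect_true(all(s$p <= s$p_prior))
  expect_true(all(s$p > 0))
  expect_true(all(s$gain > 0 & s$gain < 1))
  expect_true(all(s$r_adaptive >= 25))
  expect_true(all(s$weight >= 0.3 & s$weight <= 1))
})

test_that("constant observations are a fixed point the filter converges to", {
  fit <- rakf_filter(rep(72, 60), sq = 1, rakf_config())
  s <- tidy(fit)
  err <- abs(s$x_hat - 72)
  expect_true(all(diff(err) <= 1e-12))
  expect_lt(tail(err, 1), 1e-6)
})

test_that("filtering reduces error for stationary and ramping heart rates", {
  cfg <- rakf_config()
  better <- 0
  n_runs <- 100
  for (seed in seq_len(n_runs)) {
    set.seed(seed)
    truth <- if (seed %% 2 == 0) rep(72, 120) else seq(60, 90, length.out = 120)
    z <- truth + rnorm(120, sd = 4)
    # occasional artifacts
    idx <- sample(120, 6)
    z[idx] <- z[idx] + sample(c(-1, 1), 6, TRUE) * runif(6, 20, 50)
    z <- pmin(pmax(z, 45), 150)
    fit <- rakf_filter(z, sq = 1, cfg)
    if (mean(abs(tidy(fit)$x_hat - truth)) < mean(abs(z - truth))) {
      better <- better + 1
    }
  }
  expect_gte(better, 0.9 * n_runs)
})

test_that("posterior variance is below observation variance around a constant rate", {
  reductions <- vapply(1:100, function(seed) {
    set.seed(seed + 500)
    z <- 72 + rnorm(80, sd = 5)
    fit <- rakf_filter(z, sq = 1, rakf_config())
    var(tidy(fit)$x_hat[20:80]) < var(z[20:80])
  }, logical(1))
  expect_gte(mean(reductions), 0.99)
})

test_that("a single spike is mostly absorbed", {
  z <- rep(72, 40)
  z[20] <- 140
  fit <- rakf_filter(z, sq = 1, rakf_config())
  s <- tidy(fit)
  expect_true(s$outlier_replaced[20])
  expect_lt(max(abs(s$x_hat - 72)), 0.2 * (140 - 72))
})

test_that("empty observations give an empty fit", {
  fit <- rakf_filter(numeric(0))
  expect_equal(nrow(tidy(fit)), 0)
  expect_equal(glance(fit)$n_steps, 0)
})
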