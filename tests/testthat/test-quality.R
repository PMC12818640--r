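flat_spectrum <- function(band = c(0.75, 2.5), df = 0.01, power = 1) {
  f <- seq(band[1], band[2], by = df)
  tibble::tibble(frequency = f, power = rep(power, length(f)))
}

tone_spectrum <- function(f0, band = c(0.75, 2.5), df = 0.01) {
  sp <- flat_spectrum(band, df, power = 0)
  sp$power[which.min(abs(sp$frequency - f0))] <- 1
  sp
}

test_that("spectral power ratio: tone ~ 1, flat ~ bandwidth ratio, empty -> 0", {
  expect_equal(spectral_power_ratio(tone_spectrum(1.2), 1.2), 1)
  # flat spectrum: power in +/-0.15 Hz over total in 1.75 Hz
  expect_equal(spectral_power_ratio(flat_spectrum(), 1.5), 0.3 / 1.75,
               tolerance = 0.05)
  expect_equal(spectral_power_ratio(flat_spectrum(power = 0), 1.2), 0)
})

test_that("snr component maps dB onto [0,1] with clipping", {
  expect_equal(snr_component(tone_spectrum(1.2), 1.2), 1) # no noise -> 1
  # flat spectrum: compute the mapped value in closed form
  sp <- flat_spectrum()
  f0 <- 1.2
  sig <- sum(sp$power[abs(sp$frequency - f0) <= 0.15 |
                        abs(sp$frequency - 2 * f0) <= 0.15])
  noise <- sum(sp$power) - sig
  expected <- min(1, max(0, (10 * log10(sig / noise) + 5) / 15))
  expect_equal(snr_component(sp, f0), expected)
  expect_lt(snr_component(sp, f0), 0.5)
  # a tone 10 dB below the (concentrated, out-of-mask) noise clips to 0
  sp2 <- flat_spectrum(power = 0)
  sp2$power[which.min(abs(sp2$frequency - 1.2))] <- 1
  sp2$power[which.min(abs(sp2$frequency - 1.7))] <- 10
  expect_equal(snr_component(sp2, 1.2), 0)
})

test_that("peak stability is 1 - CV floored at zero", {
  expect_equal(peak_stability(rep(0.8, 6)), 1)
  expect_equal(peak_stability(c(0.8, 1.2)),
               1 - sd(c(0.8, 1.2)) / mean(c(0.8, 1.2)))
  expect_equal(peak_stability(c(0.2, 3, 0.1, 4)), 0)
  expect_equal(peak_stability(numeric(0)), 0)
  expect_equal(peak_stability(0.8), 0)
})

test_that("signal quality is the lambda-weighted convex combination", {
  expect_equal(signal_quality(1, 1, 1), 1)
  expect_equal(signal_quality(1, 0, 0), 0.3)
  expect_equal(signal_quality(0, 1, 0), 0.4)
  expect_equal(signal_quality(0.5, 0.5, 0.5, c(0.2, 0.5, 0.3)), 0.5)
  expect_error(signal_quality(1, 1, 1, c(0.3, 0.3, 0.3)),
               class = "rppg_config_error")
})

test_that("signal quality is monotone in each component", {
  set.seed(31)
  for (i in 1:20) {
    base <- runif(3)
    bumped <- pmin(1, base + c(0.1, 0, 0))
    expect_gte(signal_quality(bumped[1], base[2], base[3]),
               signal_quality(base[1], base[2], base[3]))
    expect_gte(signal_quality(base[1], min(1, base[2] + 0.1), base[3]),
               signal_quality(base[1], base[2], base[3]))
    expect_gte(signal_quality(base[1], base[2], min(1, base[3] + 0.1)),
               signal_quality(base[1], base[2], base[3]))
  }
})

test_that("dynamic weight floors at alpha and tracks SQ above it", {
  expect_equal(dynamic_weight(0, 0.3), 0.3)
  expect_equal(dynamic_weight(0.9, 0.3), 0.9)
  expect_equal(dynamic_weight(0.3, 0.3), 0.3)
  sq <- seq(0, 1, 0.05)
  w <- dynamic_weight(sq, 0.3)
  expect_true(all(w >= 0.3 & w <= 1))
  expect_true(all(w[sq >= 0.3] == sq[sq >= 0.3]))
  expect_error(dynamic_weight(0.5, 0), class = "rppg_config_error")
})

test_that("per-window quality scores clean windows higher than noisy ones", {
  fps <- 30
  t <- (0:1799) / fps
  clean <- sin(2 * pi * 1.2 * t)
  set.seed(32)
  noisy <- clean + rnorm(length(t), sd = 3)
  score <- function(x) {
    obs <- spectral_observations(x, fps)
    pk <- detect_peaks(x, fps)
    mean(observation_quality(obs, pk$time)$sq)
  }
  expect_gt(score(clean), score(noisy))
  expect_gt(score(clean), 0.8)
})
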