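test_that("generation is deterministic under a fixed seed", {
  a <- generate_trace(study_spec(seed = 9))
  b <- generate_trace(study_spec(seed = 9))
  expect_identical(a$trace$g, b$trace$g)
  expect_identical(a$truth, b$truth)
  c <- generate_trace(study_spec(seed = 10))
  expect_false(identical(a$trace$g, c$trace$g))
})

test_that("the noise-free trace carries the requested pulse frequency", {
  fx <- generate_trace(clean_spec(duration = 60, hr = 72))
  g <- fx$trace$g
  n <- length(g)
  sp <- Mod(fft(g - mean(g)))^2
  freqs <- (seq_len(n) - 1) * 30 / n
  half <- freqs <= 15
  f_dom <- freqs[half][which.max(sp[half])]
  expect_equal(f_dom, 1.2, tolerance = 30 / n + 1e-9)
  expect_true(all(fx$truth$hr_bpm == 72))
})

test_that("reflectance gain scales the pulse but not the noise", {
  base <- synthetic_spec(duration = 20, hr = 72, noise_sigma = 0.4,
                         baseline_drift = c(0, 0.1), artifact_bursts = NULL,
                         seed = 3)
  half <- synthetic_spec(duration = 20, hr = 72, noise_sigma = 0.4,
                         baseline_drift = c(0, 0.1), artifact_bursts = NULL,
                         reflectance_gain = 0.5, seed = 3)
  g1 <- generate_trace(base)$trace$g
  g2 <- generate_trace(half)$trace$g
  pulse1 <- attr(generate_trace(base)$trace, "clean_pulse")
  pulse2 <- attr(generate_trace(half)$trace, "clean_pulse")
  expect_equal(pulse2, 0.5 * pulse1)
  # identical seeds -> identical noise realisation: the residuals agree
  expect_equal(g1 - pulse1, g2 - pulse2)
})

test_that("artifact bursts are confined to their windows", {
  bursts <- tibble::tibble(t_start = 5, duration = 1, amplitude = 8,
                           frequency = 1.5)
  sp <- synthetic_spec(duration = 20, hr = 72, noise_sigma = 0,
                       baseline_drift = c(0, 0.1), artifact_bursts = bursts,
                       seed = 1)
  ref <- synthetic_spec(duration = 20, hr = 72, noise_sigma = 0,
                        baseline_drift = c(0, 0.1), artifact_bursts = NULL,
                        seed = 1)
  g_b <- generate_trace(sp)$trace$g
  g_r <- generate_trace(ref)$trace$g
  tt <- generate_trace(sp)$trace$time
  inside <- tt >= 5 & tt < 6
  expect_true(all(g_b[!inside] == g_r[!inside]))
  expect_gt(max(abs((g_b - g_r)[inside])), 4)
})

test_that("trajectory forms are validated and honoured", {
  expect_error(synthetic_spec(hr = 200), class = "rppg_config_error")
  ramp <- generate_trace(synthetic_spec(duration = 20, hr = c(60, 90),
                                        noise_sigma = 0, seed = 1,
                                        artifact_bursts = NULL))
  expect_equal(ramp$truth$hr_bpm[1], 60, tolerance = 0.2)
  expect_equal(tail(ramp$truth$hr_bpm, 1), 90, tolerance = 0.2)
  expect_true(all(diff(ramp$truth$hr_bpm) >= 0))
})

test_that("synthetic video embeds the trace in a detectable face patch", {
  vid <- generate_video(clean_spec(duration = 5), frame_size = c(64, 64))
  expect_length(vid$frames, 150)
  expect_equal(dim(vid$frames[[1]]), c(64, 64, 3))
  expect_true(all(vapply(vid$frames, function(f) all(f >= 0 & f <= 1),
                         logical(1))))
  expect_error(generate_video(clean_spec(duration = 2),
                              frame_size = c(32, 32)),
               class = "rppg_config_error")
})

test_that("the artifact-laden preset is seeded and in range", {
  s1 <- artifact_laden_spec(4)
  s2 <- artifact_laden_spec(4)
  expect_identical(generate_trace(s1)$trace$g, generate_trace(s2)$trace$g)
  hr <- s1$hr_trajectory(0)
  expect_gte(hr, 60)
  expect_lte(hr, 90)
  expect_true(all(s1$artifact_bursts$frequency >= 0.9 &
                    s1$artifact_bursts$frequency <= 2.2))
})

test_that("the default study fixture scores about -5 dB raw SNR", {
  snrs <- vapply(1:5, function(seed) {
    fx <- generate_trace(study_spec(seed = seed))
    trace_snr_db(fx$trace$g, trace_fps(fx$trace))
  }, numeric(1))
  expect_true(all(snrs > -8 & snrs < -2))
})
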