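# Shared fixtures: all synthetic, generated in code at test time.

# A clean sinusoidal pulse trace without noise, drift or artifacts.
clean_spec <- function(duration = 30, hr = 72, fps = 30, seed = 1) {
  synthetic_spec(duration = duration, fps = fps, hr = hr,
                 baseline_drift = c(0, 0.1), noise_sigma = 0,
                 artifact_bursts = NULL, seed = seed)
}

# The default study fixture (drift + noise + two bursts) at a given seed.
study_spec <- function(hr = 72, seed = 1) {
  synthetic_spec(hr = hr, seed = seed)
}

# Brute-force soft-threshold rule, written directly from the piecewise
# definition (independent of the vectorised implementation).
soft_threshold_oracle <- function(d, t) {
  vapply(d, function(di) {
    if (abs(di) > t) sign(di) * (abs(di) - t) else 0
  }, numeric(1))
}

expect_tibble_cols <- function(df, cols) {
  expect_true(all(cols %in% names(df)))
}
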