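#' Specification for a synthetic rPPG fixture
#'
#' Describes a ground-truthed synthetic colour trace: a quasi-sinusoidal
#' pulsatile component following a heart-rate trajectory, low-frequency
#' baseline wander (illumination drift / slow head motion), broadband Gaussian
#' sensor noise, sparse large-amplitude motion-artifact bursts, and a
#' reflectance gain mimicking melanin-dependent pulse amplitude. The pulse
#' waveform is a fundamental plus a 30 % first harmonic, which gives it the
#' asymmetric systolic shape real photoplethysmograms show and keeps peak
#' detection honest.
#'
#' @param duration Trace length in seconds.
#' @param fps Frame rate (frames/second).
#' @param hr One of: a single bpm value (constant trajectory), a length-2
#'   vector `c(from, to)` (linear ramp), or a function of time in seconds
#'   returning bpm. Values must stay within 45–150 bpm.
#' @param pulse_amplitude Peak amplitude of the pulsatile fundamental
#'   (intensity units).
#' @param baseline_drift Length-2 vector `c(amplitude, frequency_hz)` of the
#'   sinusoidal baseline wander; frequency must be below 0.3 Hz.
#' @param noise_sigma Standard deviation of the white Gaussian sensor noise.
#'   The defaults (noise, drift and bursts together) are calibrated so the
#'   raw trace scores roughly -5 dB with [trace_snr_db()]: a heavily
#'   corrupted raw signal whose corruption is dominated, as in real rPPG
#'   recordings, by illumination drift and motion rather than by sensor
#'   noise (spatial averaging over thousands of ROI pixels suppresses the
#'   latter).
#' @param artifact_bursts Data frame / tibble with columns `t_start`,
#'   `duration`, `amplitude` and optionally `frequency` (Hz): boxcar-gated
#'   oscillatory transients emulating head motion. The default two 1-s
#'   bursts at 5x the pulse amplitude use 0.5 Hz (a slow nod); rhythmic
#'   motion such as talking or rocking can be emulated with in-band
#'   frequencies (0.9-2.2 Hz), which is what makes motion artefacts so
#'   damaging to spectral heart-rate estimation.
#' @param reflectance_gain Multiplier in (0, 1] applied to the pulsatile
#'   component only (skin-tone dependent amplitude); noise is unaffected.
#' @param baseline Constant offset added to every channel.
#' @param seed Integer seed; the same spec always generates the same trace.
#' @return A `synthetic_spec` list.
#' @seealso [generate_trace()], [generate_video()]
#' @export
synthetic_spec <- function(duration = 60, fps = 30, hr = 72,
                           pulse_amplitude = 1,
                           baseline_drift = c(1.7, 0.1),
                           noise_sigma = 0.3,
                           artifact_bursts = default_bursts(duration,
                                                            pulse_amplitude),
                           reflectance_gain = 1,
                           baseline = 0,
                           seed = 1L) {
  check_number(duration, "duration", lower = 1)
  check_number(fps, "fps", lower = 1)
  check_number(pulse_amplitude, "pulse_amplitude", lower = 0)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(reflectance_gain, "reflectance_gain", lower = 1e-9, upper = 1)
  if (length(baseline_drift) != 2 || baseline_drift[2] > 0.3) {
    stop_config("`baseline_drift` must be c(amplitude, frequency) with frequency <= 0.3 Hz")
  }
  traj <- hr_trajectory_fun(hr)
  tt <- seq(0, duration, by = 1 / fps)
  hr_vals <- traj(tt)
  if (any(hr_vals < 45 | hr_vals > 150)) {
    stop_config("heart-rate trajectory must stay within 45-150 bpm")
  }
  bursts <- if (is.null(artifact_bursts)) {
    tibble::tibble(t_start = numeric(), duration = numeric(),
                   amplitude = numeric())
  } else {
    tibble::as_tibble(artifact_bursts)
  }
  structure(
    list(duration = duration, fps = fps, hr_trajectory = traj,
         pulse_amplitude = pulse_amplitude,
         baseline_drift = baseline_drift, noise_sigma = noise_sigma,
         artifact_bursts = bursts, reflectance_gain = reflectance_gain,
         baseline = baseline, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

default_bursts <- function(duration, pulse_amplitude) {
  if (duration < 45) {
    starts <- duration * c(0.35, 0.7)
  } else {
    starts <- c(15, 35)
  }
  tibble::tibble(t_start = starts, duration = 1,
                 amplitude = 5 * pulse_amplitude, frequency = 0.5)
}

#' Artifact-laden study fixture
#'
#' A seeded preset emulating an uncontrolled recording: constant heart rate
#' drawn from 60-90 bpm, the default drift, moderate broadband sensor noise,
#' and several rhythmic in-band motion bursts (0.9-2.2 Hz, the band where
#' head motion collides with the pulse). This is the regime in which the
#' denoising, outlier-rejection and quality-weighting stages each earn their
#' keep, and the fixture used for the ablation comparisons.
#'
#' @param seed Integer seed controlling the heart rate, burst placement and
#'   noise realisation.
#' @param duration,fps,noise_sigma,n_bursts Overridable study parameters.
#' @return A [synthetic_spec()].
#' @export
artifact_laden_spec <- function(seed, duration = 60, fps = 30,
                                noise_sigma = 1.2, n_bursts = 3) {
  draws <- withr_seed(seed + 10000L, function() {
    # bursts start after an artifact-free settling stretch: subjects sit
    # still at first and motion develops as the session goes on
    list(hr = stats::runif(1, 60, 90),
         starts = sort(stats::runif(n_bursts, 15, duration - 8)),
         dur = stats::runif(n_bursts, 2.5, 5),
         amp = stats::runif(n_bursts, 4, 8),
         freq = stats::runif(n_bursts, 0.9, 2.2))
  })
  keep <- c(TRUE, diff(draws$starts) > 12)
  bursts <- tibble::tibble(
    t_start = draws$starts, duration = draws$dur,
    amplitude = draws$amp, frequency = draws$freq
  )[keep, ]
  synthetic_spec(duration = duration, fps = fps, hr = round(draws$hr),
                 noise_sigma = noise_sigma, artifact_bursts = bursts,
                 seed = seed)
}

hr_trajectory_fun <- function(hr) {
  if (is.function(hr)) return(hr)
  if (is.numeric(hr) && length(hr) == 1) {
    force(hr)
    return(function(t) rep(hr, length(t)))
  }
  if (is.numeric(hr) && length(hr) == 2) {
    from <- hr[1]
    to <- hr[2]
    return(function(t) {
      span <- max(t)
      if (span == 0) return(rep(from, length(t)))
      from + (to - from) * t / span
    })
  }
  stop_config("`hr` must be a scalar, c(from, to), or a function of time")
}

#' Generate a ground-truthed synthetic colour trace
#'
#' Builds the raw trace `g(t) = baseline + gain * pulse + drift + noise +
#' bursts` described by a [synthetic_spec()]. The pulsatile component uses the
#' cumulative phase of the instantaneous heart-rate trajectory, so ramps and
#' modulations are frequency-exact. The red and blue channels carry the same
#' drift/bursts with attenuated pulse content (0.4x and 0.25x), mirroring the
#' stronger haemoglobin absorption in green.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `trace` (a [raw_trace()]) and `truth`
#'   (tibble `time`, `hr_bpm`).
#' @examples
#' fx <- generate_trace(synthetic_spec(duration = 20, noise_sigma = 0))
#' head(fx$truth)
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fps <- spec$fps
  n <- floor(spec$duration * fps)
  tt <- (seq_len(n) - 1) / fps
  hr <- spec$hr_trajectory(tt)
  # cumulative phase of the instantaneous pulse frequency hr/60
  phase <- 2 * pi * cumsum(hr / 60) / fps
  pulse <- spec$pulse_amplitude * (sin(phase) + 0.3 * sin(2 * phase))
  pulse <- spec$reflectance_gain * pulse
  drift <- spec$baseline_drift[1] *
    sin(2 * pi * spec$baseline_drift[2] * tt + pi / 3)
  burst <- numeric(n)
  if (nrow(spec$artifact_bursts) > 0) {
    for (i in seq_len(nrow(spec$artifact_bursts))) {
      b <- spec$artifact_bursts[i, ]
      sel <- tt >= b$t_start & tt < b$t_start + b$duration
      freq <- if ("frequency" %in% names(b)) b$frequency else 0.5
      burst[sel] <- burst[sel] +
        b$amplitude * sin(2 * pi * freq * (tt[sel] - b$t_start))
    }
  }
  noise <- withr_seed(spec$seed, function() {
    list(g = stats::rnorm(n, 0, spec$noise_sigma),
         r = stats::rnorm(n, 0, spec$noise_sigma),
         b = stats::rnorm(n, 0, spec$noise_sigma))
  })
  g <- spec$baseline + pulse + drift + noise$g + burst
  r <- spec$baseline + 0.40 * pulse + drift + noise$r + burst
  b <- spec$baseline + 0.25 * pulse + drift + noise$b + burst
  trace <- raw_trace(time = tt, r = r, g = g, b = b, fps = fps,
                     n_pixels = 1L, flagged = FALSE)
  attr(trace, "clean_pulse") <- pulse
  list(trace = trace, truth = tibble::tibble(time = tt, hr_bpm = hr))
}

# Run fn with a temporary RNG state seeded from `seed`, restoring the caller's
# state afterwards so generation never disturbs user-level randomness.
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic face video as a frame sequence
#'
#' Renders the trace from [generate_trace()] into a sequence of small RGB
#' frames: a rectangular "face" patch whose interior intensity follows the
#' trace (scaled into \[0, 1\]) over a darker static background. The returned
#' object carries the face box so a stub detector can drive the acquisition
#' stage end-to-end without any cascade model files.
#'
#' @param spec A [synthetic_spec()]. Intensity components are scaled by
#'   `intensity_scale` and offset to mid-grey, so keep amplitudes moderate to
#'   avoid clipping.
#' @param frame_size Length-2 integer vector `c(height, width)`, at least 64.
#' @param intensity_scale Multiplier mapping trace units to \[0, 1\] intensity.
#' @return A `frame_sequence` list: `frames` (list of H x W x 3 arrays),
#'   `fps`, `timestamps`, `face_box`, `truth`, `trace` (the injected trace).
#' @export
generate_video <- function(spec, frame_size = c(64, 64),
                           intensity_scale = 0.02) {
  if (any(frame_size < 64)) stop_config("`frame_size` must be at least 64 x 64")
  fx <- generate_trace(spec)
  h <- frame_size[1]
  w <- frame_size[2]
  # face occupies the central ~70 % of the frame
  box <- c(x = round(w * 0.15), y = round(h * 0.1),
           w = round(w * 0.7), h = round(h * 0.75))
  n <- nrow(fx$trace)
  base_frame <- array(0.2, dim = c(h, w, 3))
  rows <- (box["y"] + 1):(box["y"] + box["h"])
  cols <- (box["x"] + 1):(box["x"] + box["w"])
  frames <- vector("list", n)
  vals <- cbind(fx$trace$r, fx$trace$g, fx$trace$b)
  centred <- sweep(vals, 2, colMeans(vals))
  intens <- clamp(0.5 + intensity_scale * centred, 0, 1)
  for (i in seq_len(n)) {
    fr <- base_frame
    fr[rows, cols, 1] <- intens[i, 1]
    fr[rows, cols, 2] <- intens[i, 2]
    fr[rows, cols, 3] <- intens[i, 3]
    frames[[i]] <- fr
  }
  structure(
    list(frames = frames, fps = spec$fps, timestamps = fx$trace$time,
         face_box = box, truth = fx$truth, trace = fx$trace),
    class = "frame_sequence"
  )
}
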