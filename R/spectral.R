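# Cardiac-band isolation and sliding-window spectral observations.

#' Bandpass filter settings
#'
#' @param f_low,f_high Lower and upper cut-off frequencies in Hz
#'   (`0 < f_low < f_high`).
#' @param order Butterworth order per pass (applied forward-backward, so the
#'   effective magnitude response is squared).
#' @param label Optional stage label used in diagnostics.
#' @return A `bandpass_spec` list.
#' @export
bandpass_spec <- function(f_low, f_high, order = 4, label = NULL) {
  check_number(f_low, "f_low", lower = 1e-6)
  check_number(f_high, "f_high")
  check_number(order, "order", lower = 1, upper = 12)
  if (f_high <= f_low) stop_config("`f_high` must exceed `f_low`")
  structure(list(f_low = f_low, f_high = f_high, order = as.integer(order),
                 label = label %||% sprintf("%.2f-%.2f Hz", f_low, f_high)),
            class = "bandpass_spec")
}

#' Default wide and narrow cardiac bands
#'
#' Stage 1 is a wide 0.6-3.5 Hz pass removing baseline wander and sensor
#' noise; stage 2 narrows to 0.8-2.5 Hz, the band where heart rate dominates.
#' @return A `bandpass_spec`.
#' @export
wide_band <- function() bandpass_spec(0.6, 3.5, label = "wide")

#' @rdname wide_band
#' @export
narrow_band <- function() bandpass_spec(0.8, 2.5, label = "narrow")

#' Zero-phase Butterworth bandpass
#'
#' Designs a Butterworth bandpass and applies it forward-backward
#' (zero-phase), after reflective padding to suppress start-up transients, so
#' peak timings used by the inter-beat stage are undistorted.
#'
#' @param x Numeric signal.
#' @param spec A [bandpass_spec()].
#' @param fps Sampling rate in Hz; must exceed `2 * f_high`.
#' @return Filtered numeric signal, same length as `x`.
#' @export
bandpass_filter <- function(x, spec, fps) {
  stopifnot(inherits(spec, "bandpass_spec"))
  check_number(fps, "fps", lower = 1e-6)
  if (spec$f_high >= fps / 2) {
    stop_config(sprintf("upper cutoff %.3g Hz is not below Nyquist (%.3g Hz)",
                        spec$f_high, fps / 2))
  }
  n <- length(x)
  if (n < 8) stop_input("signal too short to filter")
  bf <- signal::butter(spec$order, c(spec$f_low, spec$f_high) / (fps / 2),
                       type = "pass")
  pad <- min(n - 1L, as.integer(ceiling(3 * fps)))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  yp <- signal::filtfilt(bf, xp)
  yp[(pad + 1):(pad + n)]
}

#' Dual-stage cardiac bandpass
#'
#' Applies the wide then the narrow Butterworth stage in sequence. The narrow
#' band must nest inside the wide band.
#'
#' @param x Numeric signal.
#' @param fps Sampling rate in Hz.
#' @param wide,narrow Stage specifications ([bandpass_spec()]).
#' @return A `filtered_signal` list: `values`, `stages`, `fps`.
#' @export
dual_stage_filter <- function(x, fps, wide = wide_band(),
                              narrow = narrow_band()) {
  if (narrow$f_low < wide$f_low || narrow$f_high > wide$f_high) {
    stop_config("the narrow band must lie inside the wide band")
  }
  y <- bandpass_filter(x, wide, fps)
  y <- bandpass_filter(y, narrow, fps)
  structure(list(values = y, stages = list(wide, narrow), fps = fps),
            class = "filtered_signal")
}

# Hann-tapered, zero-padded power spectrum of one window.
window_spectrum <- function(seg, fps, zero_pad = 4) {
  n <- length(seg)
  seg <- seg - mean(seg)
  w <- hann_window(n)
  padded <- c(seg * w, numeric((zero_pad - 1) * n))
  np <- length(padded)
  sp <- stats::fft(padded)
  half <- floor(np / 2)
  tibble::tibble(
    frequency = (seq_len(half + 1) - 1) * fps / np,
    power = Mod(sp[seq_len(half + 1)])^2
  )
}

#' Sliding-window spectral heart-rate observations
#'
#' Slides a Hann-tapered FFT window along the filtered signal; in each window
#' the dominant frequency within the physiological search band becomes the
#' observation `z = 60 * f_dom` (bpm) that feeds the Kalman stage. Spectra are
#' zero-padded for finer bin spacing and retained (over a slightly wider band
#' so the first harmonic is visible) for the signal-quality stage.
#'
#' @param x Numeric filtered signal, or a `filtered_signal`.
#' @param fps Sampling rate in Hz (ignored when `x` is a `filtered_signal`).
#' @param window_length,hop Window length and hop in seconds.
#' @param search_band Length-2 Hz band in which the dominant peak is sought;
#'   the default 0.75-2.5 Hz corresponds to 45-150 bpm.
#' @param spectrum_band Band over which spectra are retained for diagnostics
#'   and quality scoring.
#' @param zero_pad FFT zero-padding factor.
#' @return Tibble with one row per window: `k`, `t_center`, `f_dom_hz`,
#'   `z_bpm`, and a `spectrum` list-column of `(frequency, power)` tibbles.
#' @export
spectral_observations <- function(x, fps = NULL, window_length = 10, hop = 1,
                                  search_band = c(0.75, 2.5),
                                  spectrum_band = c(0.5, 5),
                                  zero_pad = 4) {
  if (inherits(x, "filtered_signal")) {
    fps <- x$fps
    x <- x$values
  }
  check_number(fps, "fps", lower = 1e-6)
  check_number(window_length, "window_length", lower = 1e-6)
  check_number(hop, "hop", lower = 1e-6)
  n <- length(x)
  duration <- n / fps
  if (window_length > duration + 1e-9) {
    stop_config("`window_length` exceeds the signal duration")
  }
  wlen <- round(window_length * fps)
  hlen <- hop * fps
  n_windows <- floor((duration - window_length) / hop + 1e-9) + 1
  spectrum_band[2] <- min(spectrum_band[2], fps / 2)
  purrr::map(seq_len(n_windows), function(k) {
    start <- round((k - 1) * hlen) + 1
    seg <- x[start:(start + wlen - 1)]
    sp <- window_spectrum(seg, fps, zero_pad)
    keep <- sp$frequency >= spectrum_band[1] & sp$frequency <= spectrum_band[2]
    sp <- sp[keep, ]
    inband <- sp$frequency >= search_band[1] & sp$frequency <= search_band[2]
    sub <- sp[inband, ]
    f_dom <- sub$frequency[which.max(sub$power)]
    tibble::tibble(
      k = k,
      t_center = (start - 1) / fps + window_length / 2,
      f_dom_hz = f_dom,
      z_bpm = 60 * f_dom,
      spectrum = list(sp)
    )
  }) |>
    dplyr::bind_rows()
}

#' Welch power spectral density (diagnostic)
#'
#' Averaged modified periodograms with Hann taper and 50 % overlap.
#'
#' @param x Numeric signal.
#' @param fps Sampling rate in Hz.
#' @param segment_length Segment length in seconds.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return Tibble `frequency`, `psd`.
#' @export
welch_psd <- function(x, fps, segment_length = 5, overlap = 0.5) {
  nseg <- round(segment_length * fps)
  if (nseg > length(x)) stop_config("`segment_length` exceeds signal duration")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- hann_window(nseg)
  norm <- sum(w^2) * fps
  acc <- NULL
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / norm
    acc <- if (is.null(acc)) p else acc + p
  }
  acc <- acc / length(starts)
  half <- floor(nseg / 2)
  tibble::tibble(frequency = (seq_len(half + 1) - 1) * fps / nseg,
                 psd = acc[seq_len(half + 1)])
}
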