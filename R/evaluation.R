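# Accuracy metrics (MAE / RMSE), decomposition-based SNR in dB, and the
# ablation-variant runner.

#' Mean absolute and root-mean-square error
#'
#' @param predicted,reference Equal-length bpm series, already time-aligned.
#' @return List `mae`, `rmse`, `n`.
#' @export
mae_rmse <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop_input("`predicted` and `reference` must have equal length")
  }
  if (length(predicted) < 1) stop_input("need at least one sample")
  err <- predicted - reference
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)), n = length(err))
}

#' Decomposition signal-to-noise ratio in dB
#'
#' Treats `filtered` as the signal component of `raw`; the noise is their
#' difference. Both series are mean-centred, then
#' `SNR = 10 log10(mean(filtered^2) / mean((raw - filtered)^2))`.
#'
#' @param raw Raw series `g(t)`.
#' @param filtered Extracted signal component `s(t)`, same length.
#' @return List `snr_db`, `p_signal`, `p_noise`, `degenerate` (`TRUE` when
#'   the noise power is zero and the ratio is reported as `Inf`).
#' @export
snr_db <- function(raw, filtered) {
  if (length(raw) != length(filtered)) {
    stop_input("`raw` and `filtered` must have equal length")
  }
  raw <- raw - mean(raw)
  filtered <- filtered - mean(filtered)
  p_signal <- mean(filtered^2)
  p_noise <- mean((raw - filtered)^2)
  if (p_noise == 0) {
    return(list(snr_db = Inf, p_signal = p_signal, p_noise = 0,
                degenerate = TRUE))
  }
  list(snr_db = 10 * log10(p_signal / p_noise), p_signal = p_signal,
       p_noise = p_noise, degenerate = FALSE)
}

#' Narrowband cardiac reference of a signal
#'
#' Extracts the cardiac component by Fourier masking: bins within
#' `halfwidth` Hz of the dominant in-band frequency (and of its first
#' harmonic) are kept, everything else is zeroed. Used as the signal
#' component when scoring a whole trace with [trace_snr_db()].
#'
#' @param x Numeric signal.
#' @param fps Sampling rate in Hz.
#' @param f0 Fundamental in Hz; `NULL` picks the dominant frequency within
#'   `search_band`.
#' @param halfwidth Mask half-width in Hz.
#' @param harmonics Number of harmonics to keep beyond the fundamental.
#' @param search_band Band in which the fundamental is sought.
#' @return List `reference` (numeric, same length) and `f0`.
#' @export
narrowband_reference <- function(x, fps, f0 = NULL, halfwidth = 0.15,
                                 harmonics = 1, search_band = c(0.75, 2.5)) {
  n <- length(x)
  xc <- x - mean(x)
  sp <- stats::fft(xc)
  freqs <- (seq_len(n) - 1) * fps / n
  freqs <- pmin(freqs, fps - freqs) # two-sided distance to DC
  if (is.null(f0)) {
    inband <- freqs >= search_band[1] & freqs <= search_band[2]
    f0 <- freqs[inband][which.max(Mod(sp[inband])^2)]
  }
  mask <- rep(FALSE, n)
  for (h in seq_len(1 + harmonics)) {
    mask <- mask | abs(freqs - h * f0) <= halfwidth
  }
  ref <- Re(stats::fft(sp * mask, inverse = TRUE)) / n
  list(reference = ref, f0 = f0)
}

#' Whole-trace SNR against its narrowband cardiac component
#'
#' Scores a signal by how much of its power is cardiac: the narrowband
#' reference from [narrowband_reference()] is the signal component and the
#' remainder is noise, combined through [snr_db()]. Applied to the raw trace
#' this is the "raw SNR"; applied to the filtered output, the "filtered
#' SNR"; their difference is the SNR improvement of the processing chain.
#'
#' @inheritParams narrowband_reference
#' @return Scalar SNR in dB.
#' @export
trace_snr_db <- function(x, fps, f0 = NULL, halfwidth = 0.15, harmonics = 1,
                         search_band = c(0.75, 2.5)) {
  nb <- narrowband_reference(x, fps, f0, halfwidth, harmonics, search_band)
  snr_db(x, nb$reference)$snr_db
}

#' Align a reference HR series onto prediction times
#'
#' Nearest-neighbour lookup of the reference at each prediction time.
#'
#' @param times Prediction times in seconds.
#' @param reference Tibble `time`, `hr_bpm`.
#' @return Numeric vector of reference bpm at `times`.
#' @export
align_reference <- function(times, reference) {
  vapply(times, function(t) {
    reference$hr_bpm[which.min(abs(reference$time - t))]
  }, numeric(1))
}

#' Evaluate an HR series against a ground-truth reference
#'
#' @param hr Tibble with `t_center` and `hr_fused_bpm` (e.g. from
#'   [hr_series()] or [run_pipeline()]).
#' @param reference Tibble `time`, `hr_bpm`.
#' @param raw,filtered Optional signals for the SNR columns.
#' @param fps Sampling rate (required with `raw`/`filtered`).
#' @return One-row tibble: `mae_bpm`, `rmse_bpm`, `n_windows`,
#'   `snr_raw_db`, `snr_filtered_db`, `snr_improvement_db`.
#' @export
evaluate_hr <- function(hr, reference, raw = NULL, filtered = NULL,
                        fps = NULL) {
  ref <- align_reference(hr$t_center, reference)
  m <- mae_rmse(hr$hr_fused_bpm, ref)
  snr_raw <- snr_filt <- NA_real_
  if (!is.null(raw) && !is.null(filtered)) {
    check_number(fps, "fps", lower = 1e-6)
    f0 <- stats::median(hr$hr_fused_bpm) / 60
    snr_raw <- trace_snr_db(raw, fps, f0 = f0)
    snr_filt <- trace_snr_db(filtered, fps, f0 = f0)
  }
  tibble::tibble(
    mae_bpm = m$mae, rmse_bpm = m$rmse, n_windows = m$n,
    snr_raw_db = snr_raw, snr_filtered_db = snr_filt,
    snr_improvement_db = snr_filt - snr_raw
  )
}

#' Pipeline ablation variants
#'
#' Runs the pipeline with stages toggled to mirror the ablation study:
#' \describe{
#'   \item{`dwt_only`}{wavelet denoising and bandpass, heart rate taken
#'     directly from the per-window spectral peak (no state tracking).}
#'   \item{`rakf_only`}{no wavelet denoising; Kalman tracking without
#'     quality weighting.}
#'   \item{`rakf_weighted`}{no wavelet denoising; Kalman tracking with
#'     quality weighting.}
#'   \item{`dwt_rakf_unweighted`}{full chain minus the quality weighting.}
#'   \item{`full`}{the complete framework.}
#' }
#'
#' @param trace A [raw_trace()].
#' @param variant Variant name.
#' @param reference Tibble `time`, `hr_bpm`.
#' @param config A [pipeline_config()] used as the base settings.
#' @return One-row tibble from [evaluate_hr()] with a `variant` column.
#' @export
run_ablation <- function(trace, variant = c("full", "dwt_only", "rakf_only",
                                            "rakf_weighted",
                                            "dwt_rakf_unweighted"),
                         reference, config = pipeline_config()) {
  variant <- match.arg(variant)
  config$variant <- variant
  res <- run_pipeline(trace, config)
  out <- evaluate_hr(res$hr, reference,
                     raw = trace_channel(trace, config$channel),
                     filtered = res$filtered$values, fps = trace_fps(trace))
  out$variant <- variant
  out
}
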