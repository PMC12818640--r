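# Signal-quality index: SQ = lambda1 * SPR + lambda2 * SNR + lambda3 * PS,
# each component normalised to [0, 1], and the dynamic correction weight
# w = max(alpha, SQ).

#' Spectral power ratio around the dominant peak
#'
#' Fraction of the in-band power concentrated within `f_dom +/- halfwidth`.
#' Near 1 for a clean single-tone pulse, small for diffuse spectra.
#'
#' @param spectrum Tibble with `frequency` (Hz) and `power` columns.
#' @param f_dom Dominant frequency in Hz.
#' @param band Length-2 Hz band over which total power is taken.
#' @param halfwidth Half-width of the peak region in Hz.
#' @return Scalar in `[0, 1]`; 0 when the band holds no power.
#' @export
spectral_power_ratio <- function(spectrum, f_dom, band = c(0.75, 2.5),
                                 halfwidth = 0.15) {
  inband <- spectrum$frequency >= band[1] & spectrum$frequency <= band[2]
  total <- sum(spectrum$power[inband])
  if (total <= 0) return(0)
  peak <- inband & abs(spectrum$frequency - f_dom) <= halfwidth
  clamp(sum(spectrum$power[peak]) / total, 0, 1)
}

#' Normalised spectral SNR component
#'
#' Ratio (in dB) of the power at the dominant peak plus its first harmonic
#' (each `+/- halfwidth`) to the remaining in-band power, mapped linearly from
#' `db_range` onto `[0, 1]` with clipping. The harmonic is included because a
#' genuine pulse is harmonic while motion artefacts rarely are. The default
#' -5..10 dB mapping saturates for a clean pulse window and floors for a
#' noise-dominated one, which is what makes the component discriminative.
#'
#' @inheritParams spectral_power_ratio
#' @param db_range dB values mapped to 0 and 1.
#' @return Scalar in `[0, 1]`; 1 when no noise power remains.
#' @export
snr_component <- function(spectrum, f_dom, band = c(0.75, 2.5),
                          halfwidth = 0.15, db_range = c(-5, 10)) {
  f <- spectrum$frequency
  sig_sel <- abs(f - f_dom) <= halfwidth | abs(f - 2 * f_dom) <= halfwidth
  inband <- f >= band[1] & f <= band[2]
  p_sig <- sum(spectrum$power[sig_sel])
  p_noise <- sum(spectrum$power[inband & !sig_sel])
  if (p_noise <= 0) return(1)
  if (p_sig <= 0) return(0)
  db <- 10 * log10(p_sig / p_noise)
  clamp((db - db_range[1]) / (db_range[2] - db_range[1]), 0, 1)
}

#' Peak-stability component from inter-beat intervals
#'
#' `PS = max(0, 1 - CV)` where CV is the coefficient of variation of the
#' inter-beat intervals in a local window. Fewer than two intervals give 0
#' (no evidence of stability).
#'
#' @param ibis Numeric inter-beat intervals in seconds.
#' @return Scalar in `[0, 1]`.
#' @export
peak_stability <- function(ibis) {
  ibis <- ibis[is.finite(ibis)]
  if (length(ibis) < 2) return(0)
  cv <- stats::sd(ibis) / mean(ibis)
  max(0, 1 - cv)
}

#' Combined signal-quality index
#'
#' Convex combination `SQ = lambda1 * SPR + lambda2 * SNR + lambda3 * PS`
#' with the empirical weights (0.3, 0.4, 0.3); the SNR term carries the
#' largest weight because frequency-domain structure is the most
#' discriminative reliability cue.
#'
#' @param spr,snr_norm,ps Components in `[0, 1]`.
#' @param lambdas Length-3 non-negative weights summing to 1.
#' @return Scalar in `[0, 1]`.
#' @export
signal_quality <- function(spr, snr_norm, ps, lambdas = c(0.3, 0.4, 0.3)) {
  if (length(lambdas) != 3 || any(lambdas < 0) ||
      abs(sum(lambdas) - 1) > 1e-9) {
    stop_config("`lambdas` must be three non-negative weights summing to 1")
  }
  comps <- c(spr, snr_norm, ps)
  if (any(comps < -1e-12 | comps > 1 + 1e-12)) {
    stop_input("quality components must lie in [0, 1]")
  }
  sum(lambdas * comps)
}

#' Dynamic correction weight
#'
#' `w = max(alpha, SQ)`: the Kalman correction is scaled by the signal
#' quality but never below the floor `alpha`, so even poor frames contribute
#' a minimal update.
#'
#' @param sq Signal-quality index in `[0, 1]`.
#' @param alpha Minimum weight in `(0, 1]`.
#' @return Scalar in `[alpha, 1]`.
#' @export
dynamic_weight <- function(sq, alpha = 0.3) {
  check_number(alpha, "alpha", lower = 1e-12, upper = 1)
  if (any(sq < -1e-12 | sq > 1 + 1e-12)) stop_input("`sq` must lie in [0, 1]")
  pmax(alpha, sq)
}

#' Per-window signal quality for a set of spectral observations
#'
#' Scores each observation window: SPR and the SNR component come from the
#' window's stored spectrum; PS comes from the inter-beat intervals of the
#' detected peaks. Two PS variants are returned: `ps` uses a trailing
#' `ps_memory`-second history of beats up to the window centre (the quantity
#' fed to the Kalman weighting), and `ps_window` uses only beats inside the
#' window itself (used for the time-domain fusion weight).
#'
#' @param observations Output of [spectral_observations()].
#' @param peak_times Peak times in seconds from [detect_peaks()] (may be
#'   empty).
#' @param window_length Window length in seconds (to match the observations).
#' @param lambdas,band,halfwidth Passed to the component functions.
#' @param ps_memory Trailing history length in seconds for the `ps`
#'   component.
#' @return Tibble `k`, `spr`, `snr_norm`, `ps`, `ps_window`, `sq`,
#'   `sq_window`.
#' @export
observation_quality <- function(observations, peak_times = numeric(),
                                window_length = 10,
                                lambdas = c(0.3, 0.4, 0.3),
                                band = c(0.75, 2.5), halfwidth = 0.15,
                                ps_memory = 10) {
  purrr::map(seq_len(nrow(observations)), function(i) {
    sp <- observations$spectrum[[i]]
    f_dom <- observations$f_dom_hz[i]
    tc <- observations$t_center[i]
    spr <- spectral_power_ratio(sp, f_dom, band, halfwidth)
    snr <- snr_component(sp, f_dom, band, halfwidth)
    hist_pk <- peak_times[peak_times >= tc - ps_memory & peak_times <= tc]
    win_pk <- peak_times[abs(peak_times - tc) <= window_length / 2]
    ps_hist <- peak_stability(diff(hist_pk))
    ps_win <- peak_stability(diff(win_pk))
    tibble::tibble(
      k = observations$k[i], spr = spr, snr_norm = snr,
      ps = ps_hist, ps_window = ps_win,
      sq = signal_quality(spr, snr, ps_hist, lambdas),
      sq_window = signal_quality(spr, snr, ps_win, lambdas)
    )
  }) |>
    dplyr::bind_rows()
}
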