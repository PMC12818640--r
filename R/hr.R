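# Time-domain heart rate from systolic peaks and inter-beat intervals, plus
# quality-weighted fusion with the spectral (Kalman-filtered) estimate.

#' Detect systolic peaks in a filtered pulse signal
#'
#' Local-maximum detection constrained by the accepted conventions: a minimum
#' peak distance of `60 / hr_band_bpm[2]` seconds (no two beats closer than
#' the fastest admissible heart rate), a minimum topographic prominence of
#' `prominence_factor` times a robust signal amplitude (IQR-based, so bursts
#' do not inflate it), and a minimum width of two samples.
#'
#' @param x Numeric filtered signal or a `filtered_signal`.
#' @param fps Sampling rate in Hz (taken from `x` when it is a
#'   `filtered_signal`).
#' @param hr_band_bpm Admissible heart-rate range in bpm.
#' @param prominence_factor Fraction of the robust amplitude a peak must
#'   protrude.
#' @param min_width Minimum peak width in samples at half prominence.
#' @return A `peak_set`: tibble `index`, `time`, `height`, `prominence` with
#'   the constraints recorded as attributes. Zero rows when nothing
#'   qualifies.
#' @export
detect_peaks <- function(x, fps = NULL, hr_band_bpm = c(45, 150),
                         prominence_factor = 0.3, min_width = 2) {
  if (inherits(x, "filtered_signal")) {
    fps <- x$fps
    x <- x$values
  }
  check_number(fps, "fps", lower = 1e-6)
  n <- length(x)
  min_dist <- max(1L, floor(60 / hr_band_bpm[2] * fps))
  # robust amplitude: IQR of a zero-mean oscillation ~ 1.414 x its amplitude
  robust_amp <- stats::IQR(x) / 1.414
  min_prom <- prominence_factor * robust_amp
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand) == 0 || robust_amp == 0) {
    return(empty_peak_set(min_dist / fps, min_prom, min_width / fps))
  }
  prom <- vapply(cand, peak_prominence, numeric(1), x = x)
  widths <- vapply(seq_along(cand), function(i) {
    half <- x[cand[i]] - prom[i] / 2
    left <- cand[i]
    while (left > 1 && x[left - 1] >= half) left <- left - 1
    right <- cand[i]
    while (right < n && x[right + 1] >= half) right <- right + 1
    right - left + 1
  }, numeric(1))
  keep <- prom >= min_prom & widths >= min_width
  cand <- cand[keep]
  prom <- prom[keep]
  # enforce minimum distance, keeping the taller peak on conflict
  ord <- order(x[cand], decreasing = TRUE)
  selected <- logical(length(cand))
  taken <- integer(0)
  for (i in ord) {
    if (all(abs(cand[i] - taken) >= min_dist)) {
      selected[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  keep_idx <- which(selected)
  ord2 <- order(cand[keep_idx])
  cand <- cand[keep_idx][ord2]
  prom <- prom[keep_idx][ord2]
  ps <- tibble::tibble(index = cand, time = (cand - 1) / fps,
                       height = x[cand], prominence = prom)
  attr(ps, "constraints") <- list(min_distance_s = min_dist / fps,
                                  min_prominence = min_prom,
                                  min_width_s = min_width / fps)
  class(ps) <- c("peak_set", class(ps))
  ps
}

empty_peak_set <- function(min_distance_s, min_prominence, min_width_s) {
  ps <- tibble::tibble(index = integer(), time = numeric(),
                       height = numeric(), prominence = numeric())
  attr(ps, "constraints") <- list(min_distance_s = min_distance_s,
                                  min_prominence = min_prominence,
                                  min_width_s = min_width_s)
  class(ps) <- c("peak_set", class(ps))
  ps
}

# Topographic prominence: height above the higher of the two key saddles
# separating the peak from higher terrain on each side.
peak_prominence <- function(i, x) {
  h <- x[i]
  left_min <- h
  j <- i - 1
  while (j >= 1 && x[j] <= h) {
    left_min <- min(left_min, x[j])
    j <- j - 1
  }
  left_base <- if (j >= 1) left_min else min(left_min, x[1])
  right_min <- h
  j <- i + 1
  n <- length(x)
  while (j <= n && x[j] <= h) {
    right_min <- min(right_min, x[j])
    j <- j + 1
  }
  right_base <- if (j <= n) right_min else min(right_min, x[n])
  h - max(left_base, right_base)
}

#' Heart rate from peak times
#'
#' Inter-beat intervals are the successive differences of the peak times;
#' the pulse frequency is the reciprocal of the mean interval and heart rate
#' is 60 times that frequency.
#'
#' @param peaks A `peak_set` from [detect_peaks()] or a numeric vector of
#'   peak times in seconds.
#' @return List `ibis`, `mean_ibi`, `f_peak`, `hr_bpm`; all `NA` (with
#'   `hr_bpm = NA`) when fewer than two peaks are available.
#' @export
hr_from_peaks <- function(peaks) {
  times <- if (is.numeric(peaks)) peaks else peaks$time
  if (length(times) < 2) {
    return(list(ibis = numeric(0), mean_ibi = NA_real_, f_peak = NA_real_,
                hr_bpm = NA_real_))
  }
  ibis <- diff(times)
  mean_ibi <- mean(ibis)
  f_peak <- 1 / mean_ibi
  list(ibis = ibis, mean_ibi = mean_ibi, f_peak = f_peak,
       hr_bpm = 60 * f_peak)
}

#' Quality-weighted fusion of time- and spectral-domain estimates
#'
#' `hr = (sq_time * hr_time + sq_spectral * hr_spectral) /
#' (sq_time + sq_spectral)`; an absent estimate (or one with zero quality)
#' leaves the other as the result, so the more reliable source always
#' contributes.
#'
#' @param hr_time,hr_spectral Estimates in bpm (`NA` = absent).
#' @param sq_time,sq_spectral Quality weights in `[0, 1]`.
#' @return Fused bpm, between the two inputs; `NA` if both are absent.
#' @export
fuse_estimates <- function(hr_time, sq_time, hr_spectral, sq_spectral) {
  t_ok <- is.finite(hr_time) && is.finite(sq_time) && sq_time > 0
  s_ok <- is.finite(hr_spectral) && is.finite(sq_spectral) && sq_spectral > 0
  if (!t_ok && !s_ok) {
    if (is.finite(hr_spectral)) return(hr_spectral)
    if (is.finite(hr_time)) return(hr_time)
    return(NA_real_)
  }
  if (!t_ok) return(hr_spectral)
  if (!s_ok) return(hr_time)
  (sq_time * hr_time + sq_spectral * hr_spectral) / (sq_time + sq_spectral)
}

#' Per-window fused heart-rate series
#'
#' Combines, for each observation window, the time-domain estimate (peaks of
#' the filtered signal inside the window) with the spectral-path estimate
#' (the Kalman posterior), each weighted by its signal quality. Time-domain
#' estimates falling outside the admissible band are treated as absent, and
#' the fused output is clamped to the band.
#'
#' @param observations Tibble from [spectral_observations()].
#' @param rakf_fit A `rakf_fit` run on those observations.
#' @param quality Tibble from [observation_quality()].
#' @param peaks A `peak_set` detected on the same filtered signal.
#' @param window_length Window length in seconds.
#' @param hr_band_bpm Admissible band; fused output is clamped to it.
#' @param ibi_cv_max Physiological validity gate: a window whose inter-beat
#'   intervals vary by more than this coefficient of variation is treated as
#'   having no usable time-domain estimate. Resting sinus rhythm varies well
#'   below 25 % over ten seconds, so larger spreads indicate spurious peaks
#'   rather than beats.
#' @return Tibble `t_center`, `hr_time_bpm`, `hr_spectral_bpm`,
#'   `hr_fused_bpm`, `sq_time`, `sq_spectral`.
#' @export
hr_series <- function(observations, rakf_fit, quality, peaks,
                      window_length = 10, hr_band_bpm = c(45, 150),
                      ibi_cv_max = 0.25) {
  steps <- tidy(rakf_fit)
  stopifnot(nrow(steps) == nrow(observations),
            nrow(quality) == nrow(observations))
  peak_times <- peaks$time
  purrr::map(seq_len(nrow(observations)), function(i) {
    tc <- observations$t_center[i]
    win_pk <- peak_times[abs(peak_times - tc) <= window_length / 2]
    est <- hr_from_peaks(win_pk)
    ht <- est$hr_bpm
    if (is.finite(ht) && (ht < hr_band_bpm[1] || ht > hr_band_bpm[2])) {
      ht <- NA_real_
    }
    if (is.finite(ht) && length(est$ibis) >= 2) {
      cv <- stats::sd(est$ibis) / mean(est$ibis)
      if (cv > ibi_cv_max) ht <- NA_real_
    }
    sq_t <- if (is.finite(ht)) quality$sq_window[i] else 0
    hs <- steps$x_hat[i]
    sq_s <- quality$sq[i]
    fused <- fuse_estimates(ht, sq_t, hs, sq_s)
    tibble::tibble(
      t_center = tc,
      hr_time_bpm = ht,
      hr_spectral_bpm = hs,
      hr_fused_bpm = clamp(fused, hr_band_bpm[1], hr_band_bpm[2]),
      sq_time = sq_t, sq_spectral = sq_s
    )
  }) |>
    dplyr::bind_rows()
}
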