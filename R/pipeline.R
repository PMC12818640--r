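# Configuration and end-to-end orchestration: trace -> denoise -> dual
# bandpass -> spectral observations -> quality -> RAKF -> peak fusion.

#' Pipeline configuration
#'
#' Collects every stage parameter with the framework defaults: basal
#' measurement noise `r0 = 25` bpm^2, process noise `q = 2e-4` Hz^2 (0.72
#' bpm^2) per step, quality weights `lambdas = (0.3, 0.4, 0.3)`, wide band
#' 0.6-3.5 Hz, narrow band 0.8-2.5 Hz, admissible heart rates 45-150 bpm.
#'
#' @param channel Colour channel feeding the signal chain (green by
#'   default; it carries the strongest haemoglobin absorption signature).
#' @param wavelet_family,wavelet_j Wavelet family and decomposition depth
#'   (`NULL` = pick from the frame rate, see [default_wavelet_level()]).
#' @param f_wide,f_narrow Length-2 Hz cut-offs of the two bandpass stages.
#' @param filter_order Butterworth order per stage.
#' @param window_length,hop Spectral observation window and hop in seconds.
#' @param hr_band_bpm Admissible heart-rate range in bpm.
#' @param lambdas Quality-index weights (SPR, SNR, PS).
#' @param r0,q,beta,alpha,outlier_window,outlier_c,t_out_floor Kalman
#'   constants, see [rakf_config()].
#' @param prominence_factor Peak-detection prominence fraction.
#' @param variant Ablation variant, see [run_ablation()].
#' @param roi_tiles,redetect_every Acquisition parameters (when starting
#'   from video frames).
#' @param seed Seed recorded with the run (the signal chain itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(channel = "g",
                            wavelet_family = "db4", wavelet_j = NULL,
                            f_wide = c(0.6, 3.5), f_narrow = c(0.8, 2.5),
                            filter_order = 4,
                            window_length = 10, hop = 1,
                            hr_band_bpm = c(45, 150),
                            lambdas = c(0.3, 0.4, 0.3),
                            r0 = 25, q = 2e-4 * 60^2, beta = 10, alpha = 0.3,
                            outlier_window = 5, outlier_c = 3,
                            t_out_floor = 5,
                            prominence_factor = 0.3,
                            variant = "full",
                            roi_tiles = 2, redetect_every = 30,
                            seed = 1L) {
  cfg <- list(channel = channel, wavelet_family = wavelet_family,
              wavelet_j = wavelet_j, f_wide = f_wide, f_narrow = f_narrow,
              filter_order = filter_order, window_length = window_length,
              hop = hop, hr_band_bpm = hr_band_bpm, lambdas = lambdas,
              r0 = r0, q = q, beta = beta, alpha = alpha,
              outlier_window = outlier_window, outlier_c = outlier_c,
              t_out_floor = t_out_floor,
              prominence_factor = prominence_factor, variant = variant,
              roi_tiles = roi_tiles, redetect_every = redetect_every,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every documented invariant and returns the violations instead of
#' throwing, so configurations can be linted before a long run.
#'
#' @param config A [pipeline_config()].
#' @return Tibble with columns `field`, `message`; zero rows when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(field, message) {
    v[[length(v) + 1]] <<- tibble::tibble(field = field, message = message)
  }
  if (!config$channel %in% c("r", "g", "b")) {
    bad("channel", "channel must be one of r, g, b")
  }
  ok_band <- function(b) length(b) == 2 && all(is.finite(b)) && b[1] > 0 &&
    b[1] < b[2]
  if (!ok_band(config$f_wide)) bad("f_wide", "wide band needs 0 < f_low < f_high")
  if (!ok_band(config$f_narrow)) {
    bad("f_narrow", "narrow band needs 0 < f_low < f_high")
  } else if (ok_band(config$f_wide) &&
             (config$f_narrow[1] < config$f_wide[1] ||
              config$f_narrow[2] > config$f_wide[2])) {
    bad("f_narrow", "narrow band must nest inside the wide band")
  }
  if (length(config$lambdas) != 3 || any(config$lambdas < 0) ||
      abs(sum(config$lambdas) - 1) > 1e-9) {
    bad("lambdas",
        "quality weights must be three non-negative values summing to 1 (the SQ index is a normalised convex combination)")
  }
  for (f in c("r0", "q", "window_length", "hop")) {
    if (!is.numeric(config[[f]]) || config[[f]] <= 0) {
      bad(f, sprintf("%s must be positive", f))
    }
  }
  if (!identical(config$beta, Inf) &&
      (!is.numeric(config$beta) || config$beta <= 0)) {
    bad("beta", "beta must be positive (or Inf to disable adaptation)")
  }
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha > 1) {
    bad("alpha", "alpha must lie in (0, 1]")
  }
  if (!(length(config$hr_band_bpm) == 2 &&
        config$hr_band_bpm[1] < config$hr_band_bpm[2])) {
    bad("hr_band_bpm", "heart-rate band must be increasing")
  }
  if (!config$variant %in% c("full", "dwt_only", "rakf_only",
                             "rakf_weighted", "dwt_rakf_unweighted")) {
    bad("variant", "unknown ablation variant")
  }
  if (!is.null(config$wavelet_j) &&
      (config$wavelet_j < 1 || config$wavelet_j > 12)) {
    bad("wavelet_j", "wavelet level must be in 1..12")
  }
  dplyr::bind_rows(v)
}

#' Write / read a configuration as flat JSON
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  for (nm in names(raw)) {
    if (nm %in% names(cfg)) cfg[[nm]] <- raw[[nm]]
  }
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full heart-rate pipeline on a trace
#'
#' Executes (subject to the ablation variant) wavelet denoising, dual-stage
#' bandpass filtering, sliding-window spectral observations, signal-quality
#' scoring, residual-adaptive Kalman filtering, and peak/spectral fusion.
#'
#' @param trace A [raw_trace()] (or path to a trace CSV).
#' @param config A [pipeline_config()].
#' @param reference Optional ground-truth tibble `time`, `hr_bpm`; when
#'   given, an evaluation row is attached.
#' @return An `rppg_result` list: `hr` (per-window tibble), `observations`,
#'   `quality`, `rakf` (fit or `NULL`), `peaks`, `denoised`, `filtered`,
#'   `evaluation` (or `NULL`), `config`.
#' @examples
#' fx <- generate_trace(synthetic_spec(duration = 30, noise_sigma = 0.2,
#'                                     artifact_bursts = NULL))
#' res <- run_pipeline(fx$trace, pipeline_config(window_length = 8))
#' head(res$hr)
#' @export
run_pipeline <- function(trace, config = pipeline_config(),
                         reference = NULL) {
  if (is.character(trace)) trace <- read_trace_csv(trace)
  if (!is_raw_trace(trace)) stop_input("`trace` must be a raw_trace (or CSV path)")
  violations <- validate_config(config)
  if (nrow(violations) > 0) {
    stop_config(paste0("invalid configuration: ",
                       paste(violations$field, violations$message,
                             sep = ": ", collapse = "; ")))
  }
  fps <- trace_fps(trace)
  x <- trace_channel(trace, config$channel)
  use_dwt <- config$variant %in% c("full", "dwt_only", "dwt_rakf_unweighted")
  use_rakf <- config$variant != "dwt_only"
  use_weight <- config$variant %in% c("full", "rakf_weighted")

  denoised <- NULL
  if (use_dwt) {
    wspec <- wavelet_spec(config$wavelet_family, config$wavelet_j)
    denoised <- dwt_denoise(x, wspec, fps = fps)
    y <- denoised$values
  } else {
    y <- x
  }
  filtered <- dual_stage_filter(
    y, fps,
    wide = bandpass_spec(config$f_wide[1], config$f_wide[2],
                         config$filter_order, "wide"),
    narrow = bandpass_spec(config$f_narrow[1], config$f_narrow[2],
                           config$filter_order, "narrow")
  )
  search_band <- config$hr_band_bpm / 60
  observations <- spectral_observations(
    filtered, window_length = config$window_length, hop = config$hop,
    search_band = search_band
  )
  peaks <- detect_peaks(filtered, hr_band_bpm = config$hr_band_bpm,
                        prominence_factor = config$prominence_factor)
  quality <- observation_quality(
    observations, peak_times = peaks$time,
    window_length = config$window_length, lambdas = config$lambdas,
    band = search_band
  )
  rcfg <- rakf_config(r0 = config$r0, q = config$q, beta = config$beta,
                      alpha = config$alpha,
                      outlier_window = config$outlier_window,
                      outlier_c = config$outlier_c,
                      t_out_floor = config$t_out_floor,
                      weighted = use_weight)
  fit <- NULL
  if (use_rakf) {
    fit <- rakf_filter(observations, sq = quality$sq, rcfg)
    hr <- hr_series(observations, fit, quality, peaks,
                    window_length = config$window_length,
                    hr_band_bpm = config$hr_band_bpm)
  } else {
    # spectral peak only: no tracking, no fusion
    hr <- tibble::tibble(
      t_center = observations$t_center,
      hr_time_bpm = NA_real_,
      hr_spectral_bpm = observations$z_bpm,
      hr_fused_bpm = clamp(observations$z_bpm, config$hr_band_bpm[1],
                           config$hr_band_bpm[2]),
      sq_time = 0, sq_spectral = quality$sq
    )
  }
  evaluation <- NULL
  if (!is.null(reference)) {
    evaluation <- evaluate_hr(hr, reference, raw = x,
                              filtered = filtered$values, fps = fps)
  }
  structure(
    list(hr = hr, observations = observations, quality = quality,
         rakf = fit, peaks = peaks, denoised = denoised,
         filtered = filtered, trace = trace, evaluation = evaluation,
         config = config),
    class = "rppg_result"
  )
}

#' @export
print.rppg_result <- function(x, ...) {
  cat(sprintf("<rppg_result> variant=%s, %d windows, median HR %.1f bpm\n",
              x$config$variant, nrow(x$hr),
              stats::median(x$hr$hr_fused_bpm, na.rm = TRUE)))
  if (!is.null(x$evaluation)) {
    cat(sprintf("  MAE %.2f bpm, RMSE %.2f bpm (n=%d)\n",
                x$evaluation$mae_bpm, x$evaluation$rmse_bpm,
                x$evaluation$n_windows))
  }
  invisible(x)
}

#' Sensitivity sweep over tuning parameters
#'
#' Re-runs the pipeline on a fixed trace across a grid of one-parameter
#' perturbations (wavelet depth `J`, minimum weight `alpha`, residual
#' sensitivity `beta`, outlier floor `t_out_floor`) and reports the MAE of
#' each setting against the reference.
#'
#' @param trace A [raw_trace()].
#' @param reference Tibble `time`, `hr_bpm`.
#' @param grid Named list mapping parameter names (`wavelet_j`, `alpha`,
#'   `beta`, `t_out_floor`) to value vectors.
#' @param config Base configuration.
#' @return Tibble `parameter`, `value`, `mae_bpm`, `rmse_bpm`.
#' @export
sensitivity_sweep <- function(trace, reference,
                              grid = list(wavelet_j = 3:6,
                                          alpha = seq(0.1, 0.6, 0.1)),
                              config = pipeline_config()) {
  rows <- list()
  for (param in names(grid)) {
    for (value in grid[[param]]) {
      cfg <- config
      cfg[[param]] <- value
      res <- run_pipeline(trace, cfg, reference = reference)
      rows[[length(rows) + 1]] <- tibble::tibble(
        parameter = param, value = value,
        mae_bpm = res$evaluation$mae_bpm,
        rmse_bpm = res$evaluation$rmse_bpm
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write the per-window HR series as CSV
#'
#' @param result An `rppg_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hr_csv <- function(result, path) {
  df <- result$hr
  names(df) <- c("t_center_s", "hr_time_bpm", "hr_spectral_bpm",
                 "hr_fused_bpm", "sq_time", "sq_spectral")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
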