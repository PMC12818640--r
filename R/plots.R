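# ggplot2 visualisations for traces, filter fits and pipeline results.

#' @export
autoplot.rppg_trace <- function(object, channels = c("r", "g", "b"), ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("time", intersect(channels, c("r", "g", "b")))],
    -"time", names_to = "channel", values_to = "intensity"
  )
  df <- dplyr::filter(df, is.finite(.data$intensity))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$intensity,
                                   colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(r = "#c0392b", g = "#1e8449",
                                            b = "#2471a3")) +
    ggplot2::labs(x = "time (s)", y = "mean ROI intensity",
                  title = "Raw rPPG trace") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rakf_fit <- function(object, ...) {
  s <- tidy(object)
  df <- tidyr::pivot_longer(
    s[c("t_center", "z_raw", "x_hat")], -"t_center",
    names_to = "series", values_to = "bpm"
  )
  labels <- c(z_raw = "spectral observation", x_hat = "filtered estimate")
  df$series <- labels[df$series]
  ggplot2::ggplot(df, ggplot2::aes(.data$t_center, .data$bpm,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = dplyr::filter(s, .data$outlier_replaced),
      ggplot2::aes(.data$t_center, .data$z_raw),
      inherit.aes = FALSE, shape = 4, colour = "#7f8c8d"
    ) +
    ggplot2::labs(x = "time (s)", y = "heart rate (bpm)",
                  colour = NULL,
                  title = "Residual-adaptive Kalman tracking",
                  subtitle = "crosses: observations replaced by the rolling median") +
    ggplot2::theme_minimal()
}

#' Plot the fused heart-rate series of a pipeline run
#'
#' @param result An `rppg_result`.
#' @param reference Optional tibble `time`, `hr_bpm` overlaid as ground
#'   truth.
#' @return A ggplot object.
#' @export
plot_hr_series <- function(result, reference = NULL) {
  hr <- result$hr
  p <- ggplot2::ggplot(hr, ggplot2::aes(.data$t_center)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$hr_fused_bpm,
                                    colour = "fused")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$hr_time_bpm,
                                     colour = "time-domain"), size = 0.7,
                        na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$hr_spectral_bpm,
                                    colour = "spectral (RAKF)"),
                       linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "heart rate (bpm)", colour = NULL,
                  title = "Estimated heart rate") +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_line(
      data = reference,
      ggplot2::aes(.data$time, .data$hr_bpm, colour = "reference"),
      linewidth = 0.3
    )
  }
  p
}

#' Plot the signal at each processing stage
#'
#' Raw channel, wavelet-denoised signal and dual-stage filtered output on a
#' shared time axis (faceted).
#'
#' @param result An `rppg_result`.
#' @return A ggplot object.
#' @export
plot_signal_stages <- function(result) {
  tr <- result$trace
  x <- trace_channel(tr, result$config$channel)
  stages <- list(raw = x - mean(x))
  if (!is.null(result$denoised)) {
    stages$denoised <- result$denoised$values - mean(result$denoised$values)
  }
  stages$filtered <- result$filtered$values
  df <- dplyr::bind_rows(lapply(names(stages), function(nm) {
    tibble::tibble(time = tr$time, stage = nm, value = stages[[nm]])
  }))
  df$stage <- factor(df$stage, levels = names(stages))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_wrap(~stage, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Signal-processing stages") +
    ggplot2::theme_minimal()
}
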