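#' Construct a raw colour trace
#'
#' A raw trace holds the per-frame spatial averages of the red, green and blue
#' channels over the facial regions of interest, i.e. the raw rPPG signal
#' before any denoising. It is an ordinary tibble (columns `time`, `r`, `g`,
#' `b`, `n_pixels`, `flagged`) carrying the frame rate as an attribute, so it
#' pipes through dplyr verbs unchanged.
#'
#' @param time Sample times in seconds, strictly increasing.
#' @param r,g,b Mean channel intensities per frame.
#' @param fps Frame rate in frames/second (> 0).
#' @param n_pixels Number of ROI pixels averaged per frame (> 0).
#' @param flagged Logical, `TRUE` where face detection failed and the previous
#'   ROI layout was carried forward.
#' @return A `rppg_trace` tibble.
#' @examples
#' tr <- raw_trace(time = (0:9) / 30, g = sin(1:10), fps = 30)
#' trace_fps(tr)
#' @export
raw_trace <- function(time, r = NULL, g, b = NULL, fps,
                      n_pixels = NA_integer_, flagged = FALSE) {
  check_number(fps, "fps", lower = 1e-9)
  n <- length(time)
  if (n < 1L) stop_input("a trace needs at least one sample")
  if (length(g) != n) stop_input("`time` and `g` must have equal length")
  if (is.unsorted(time, strictly = TRUE)) {
    stop_input("`time` must be strictly increasing")
  }
  r <- r %||% rep(NA_real_, n)
  b <- b %||% rep(NA_real_, n)
  if (!all(is.finite(g))) stop_input("`g` must be finite")
  out <- tibble::tibble(
    time = as.numeric(time), r = as.numeric(r), g = as.numeric(g),
    b = as.numeric(b),
    n_pixels = rep_len(as.integer(n_pixels), n),
    flagged = rep_len(as.logical(flagged), n)
  )
  new_rppg_trace(out, fps)
}

new_rppg_trace <- function(df, fps) {
  structure(df, fps = as.numeric(fps),
            class = c("rppg_trace", class(tibble::tibble())))
}

#' Frame rate of a trace
#' @param trace A [raw_trace()] tibble.
#' @return Frames per second as a scalar.
#' @export
trace_fps <- function(trace) {
  fps <- attr(trace, "fps", exact = TRUE)
  if (is.null(fps)) stop_input("not a trace: missing `fps` attribute")
  fps
}

#' Extract one channel of a trace as a numeric vector
#' @inheritParams trace_fps
#' @param channel One of `"r"`, `"g"`, `"b"`.
#' @return Numeric vector of mean intensities.
#' @export
trace_channel <- function(trace, channel = c("g", "r", "b")) {
  channel <- match.arg(channel)
  x <- trace[[channel]]
  if (is.null(x) || all(is.na(x))) {
    stop_input(sprintf("trace has no `%s` channel", channel))
  }
  as.numeric(x)
}

#' Read / write a trace as CSV
#'
#' The on-disk format has columns `time_s, r, g, b, n_pixels, flagged` and a
#' `# fps: <value>` comment header so the file is self-describing.
#'
#' @param trace A [raw_trace()].
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a `rppg_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  df <- tibble::tibble(
    time_s = trace$time, r = trace$r, g = trace$g, b = trace$b,
    n_pixels = trace$n_pixels, flagged = trace$flagged
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps: %.10g", trace_fps(trace)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  first <- readLines(path, n = 1L)
  fps <- NA_real_
  if (grepl("^#\\s*fps:", first)) {
    fps <- as.numeric(sub("^#\\s*fps:\\s*", "", first))
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "g") %in% names(df))) {
    stop_input("trace CSV needs at least `time_s` and `g` columns")
  }
  if (!is.finite(fps)) {
    dt <- diff(df$time_s)
    fps <- 1 / stats::median(dt)
  }
  raw_trace(
    time = df$time_s, r = df$r %||% NULL, g = df$g, b = df$b %||% NULL,
    fps = fps,
    n_pixels = if ("n_pixels" %in% names(df)) df$n_pixels else NA_integer_,
    flagged = if ("flagged" %in% names(df)) df$flagged else FALSE
  )
}

#' Read a ground-truth heart-rate reference
#'
#' Accepts a CSV (columns `time_s`/`time` and `hr_bpm`/`hr`) or an `.xlsx`
#' workbook with the same column names on its first sheet (ECG references are
#' commonly exported as spreadsheets).
#'
#' @param path File path ending in `.csv` or `.xlsx`.
#' @return Tibble with columns `time` (s) and `hr_bpm`.
#' @export
read_reference <- function(path) {
  if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_input("reading .xlsx references requires the `readxl` package")
    }
    df <- as.data.frame(readxl::read_excel(path))
  } else {
    df <- utils::read.csv(path, comment.char = "#")
  }
  names(df) <- tolower(names(df))
  time_col <- intersect(c("time_s", "time", "t"), names(df))[1]
  hr_col <- intersect(c("hr_bpm", "hr", "bpm", "heart_rate"), names(df))[1]
  if (is.na(time_col) || is.na(hr_col)) {
    stop_input("reference needs a time column and an hr column")
  }
  tibble::tibble(time = as.numeric(df[[time_col]]),
                 hr_bpm = as.numeric(df[[hr_col]]))
}
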