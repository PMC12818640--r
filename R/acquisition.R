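# Frame-sequence acquisition: face detection (pluggable), ROI geometry,
# sub-ROI tiling and spatial averaging into a raw colour trace.

#' Face-detector interfaces
#'
#' A detector is a function `f(frame)` returning a face box
#' `c(x, y, w, h)` (0-based, half-open pixel rectangle) or `NULL` when no
#' face is found. Two constructors are provided:
#'
#' * `detector_stub(box)` always reports the given box — used with synthetic
#'   videos whose face position is known, so tests need no cascade model
#'   files.
#' * `detector_bright_patch(min_contrast)` is a simple luminance-based
#'   detector for synthetic scenes: it finds the bounding box of the largest
#'   connected region brighter than the frame median. Real deployments
#'   should plug in a cascade or DNN detector behind the same interface.
#'
#' @param box Length-4 numeric `c(x, y, w, h)`.
#' @param min_contrast Minimum luminance difference between patch and
#'   background for a detection to be reported.
#' @return A detector function.
#' @export
detector_stub <- function(box) {
  force(box)
  function(frame) box
}

#' @rdname detector_stub
#' @export
detector_bright_patch <- function(min_contrast = 0.05) {
  function(frame) {
    lum <- frame_luminance(frame)
    thr <- stats::median(lum)
    mask <- lum > thr + min_contrast / 2
    if (!any(mask)) return(NULL)
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    if (max(lum[mask]) - thr < min_contrast) return(NULL)
    c(x = cols[1] - 1, y = rows[1] - 1,
      w = cols[2] - cols[1] + 1, h = rows[2] - rows[1] + 1)
  }
}

frame_luminance <- function(frame) {
  if (length(dim(frame)) == 3) {
    0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  } else {
    frame
  }
}

#' Detect a face in one frame
#'
#' Runs the detector and clips the reported box to the frame bounds; boxes
#' with no interior after clipping count as no detection.
#'
#' @param frame H x W x 3 array (or H x W grayscale) of intensities.
#' @param detector A detector function (see [detector_stub()]).
#' @return Named numeric `c(x, y, w, h)` or `NULL`.
#' @export
detect_face <- function(frame, detector) {
  d <- dim(frame)
  if (is.null(d) || !(length(d) %in% c(2, 3))) {
    stop_input("frame must be an H x W or H x W x 3 array")
  }
  box <- detector(frame)
  if (is.null(box)) return(NULL)
  h <- d[1]
  w <- d[2]
  x0 <- clamp(box[1], 0, w)
  y0 <- clamp(box[2], 0, h)
  x1 <- clamp(box[1] + box[3], 0, w)
  y1 <- clamp(box[2] + box[4], 0, h)
  if (x1 - x0 <= 0 || y1 - y0 <= 0) return(NULL)
  c(x = unname(x0), y = unname(y0), w = unname(x1 - x0), h = unname(y1 - y0))
}

#' Contrast enhancement for detection only
#'
#' Converts the frame to grayscale luminance and applies contrast-limited
#' adaptive histogram equalisation (CLAHE). The enhanced copy is used only
#' to help the face detector in poor light; the RGB values that enter the
#' spatial average are never modified.
#'
#' @param frame H x W x 3 array or grayscale matrix with values in `[0, 1]`.
#' @param clip_limit CLAHE clip limit.
#' @param tiles Number of tiles per dimension.
#' @return Enhanced grayscale matrix in `[0, 1]`.
#' @export
enhance_for_detection <- function(frame, clip_limit = 2, tiles = 8) {
  lum <- frame_luminance(frame)
  if (diff(range(lum)) < 1e-12) return(lum) # nothing to enhance
  if (requireNamespace("EBImage", quietly = TRUE)) {
    nx <- max(2L, min(tiles, floor(ncol(lum) / 8)))
    ny <- max(2L, min(tiles, floor(nrow(lum) / 8)))
    out <- EBImage::clahe(EBImage::Image(t(lum)), nx = nx, ny = ny,
                          limit = clip_limit)
    out <- t(EBImage::imageData(out))
  } else {
    # global histogram stretch fallback when EBImage is unavailable
    out <- (lum - min(lum)) / diff(range(lum))
  }
  clamp(out, 0, 1)
}

#' Forehead / cheek ROI layout inside a face box
#'
#' The forehead is an upper central band and the cheeks lower lateral
#' patches, each expressed as fractions of the face box and then tiled into
#' `tiles x tiles` sub-ROIs so uneven illumination in one tile cannot
#' dominate the average.
#'
#' @param face_box Named numeric `c(x, y, w, h)`, positive area.
#' @param geometry Named list of fractional rectangles
#'   `c(x0, x1, y0, y1)` per region; see `default_roi_geometry()`.
#' @param tiles Sub-ROI grid size per region (`tiles = 1` keeps the region
#'   whole).
#' @param source_frame_index Frame index the layout was computed from.
#' @return A `roi_layout` list with `face_box`, `regions`, `sub_rois`.
#' @export
layout_rois <- function(face_box, geometry = default_roi_geometry(),
                        tiles = 2, source_frame_index = NA_integer_) {
  if (face_box["w"] <= 0 || face_box["h"] <= 0) {
    stop_input("`face_box` must have positive area")
  }
  regions <- lapply(geometry, function(fr) {
    c(x = face_box[["x"]] + fr[["x0"]] * face_box[["w"]],
      y = face_box[["y"]] + fr[["y0"]] * face_box[["h"]],
      w = (fr[["x1"]] - fr[["x0"]]) * face_box[["w"]],
      h = (fr[["y1"]] - fr[["y0"]]) * face_box[["h"]])
  })
  regions <- lapply(regions, function(r) {
    r[c("x", "y")] <- floor(r[c("x", "y")])
    r[c("w", "h")] <- pmax(floor(r[c("w", "h")]), 0)
    r
  })
  if (any(vapply(regions, function(r) r[["w"]] < tiles || r[["h"]] < tiles,
                 logical(1)))) {
    stop_input("face box too small to tile the requested regions")
  }
  sub_rois <- lapply(regions, tile_region, tiles = tiles)
  structure(list(face_box = face_box, regions = regions,
                 sub_rois = sub_rois,
                 source_frame_index = source_frame_index),
            class = "roi_layout")
}

#' @rdname layout_rois
#' @export
default_roi_geometry <- function() {
  list(
    forehead = c(x0 = 0.20, x1 = 0.80, y0 = 0.05, y1 = 0.25),
    left_cheek = c(x0 = 0.15, x1 = 0.45, y0 = 0.55, y1 = 0.80),
    right_cheek = c(x0 = 0.55, x1 = 0.85, y0 = 0.55, y1 = 0.80)
  )
}

# Split a rectangle into a tiles x tiles grid of disjoint integer tiles
# covering it exactly.
tile_region <- function(region, tiles) {
  xs <- round(seq(region[["x"]], region[["x"]] + region[["w"]],
                  length.out = tiles + 1))
  ys <- round(seq(region[["y"]], region[["y"]] + region[["h"]],
                  length.out = tiles + 1))
  out <- list()
  for (i in seq_len(tiles)) {
    for (j in seq_len(tiles)) {
      out[[length(out) + 1]] <- c(x = xs[i], y = ys[j],
                                  w = xs[i + 1] - xs[i],
                                  h = ys[j + 1] - ys[j])
    }
  }
  out
}

#' Spatial average of one channel over the ROI layout
#'
#' Mean pixel intensity over the union of all sub-ROI pixels (equivalently,
#' the pixel-count-weighted mean of per-tile means).
#'
#' @param frame H x W x 3 array.
#' @param roi_layout A [layout_rois()] result.
#' @param channel `"r"`, `"g"` or `"b"`.
#' @return List `mean`, `n_pixels`.
#' @export
spatial_average <- function(frame, roi_layout, channel = c("g", "r", "b")) {
  channel <- match.arg(channel)
  ch <- match(channel, c("r", "g", "b"))
  total <- 0
  n <- 0L
  for (region in roi_layout$sub_rois) {
    for (tile in region) {
      if (tile[["w"]] <= 0 || tile[["h"]] <= 0) next
      rows <- (tile[["y"]] + 1):(tile[["y"]] + tile[["h"]])
      cols <- (tile[["x"]] + 1):(tile[["x"]] + tile[["w"]])
      vals <- frame[rows, cols, ch]
      total <- total + sum(vals)
      n <- n + length(vals)
    }
  }
  if (n == 0L) stop_input("ROI layout selects no pixels")
  list(mean = total / n, n_pixels = n)
}

#' Extract a raw colour trace from a frame sequence
#'
#' For every frame, averages each colour channel over the facial ROIs. The
#' face is re-detected every `redetect_every` frames (optionally on a
#' CLAHE-enhanced grayscale copy); between re-detections, and on frames
#' where detection fails, the last layout is carried forward and the frame
#' flagged.
#'
#' @param seq A `frame_sequence` (list with `frames`, `fps`, `timestamps`)
#'   such as from [generate_video()] or [read_frames_dir()].
#' @param detector A detector function; defaults to the stub with the
#'   sequence's own `face_box` when present, else [detector_bright_patch()].
#' @param geometry ROI geometry fractions.
#' @param tiles Sub-ROI grid size.
#' @param redetect_every Re-detection cadence in frames.
#' @param enhance Apply [enhance_for_detection()] before detecting.
#' @return A [raw_trace()].
#' @export
extract_trace <- function(seq, detector = NULL,
                          geometry = default_roi_geometry(), tiles = 2,
                          redetect_every = 30, enhance = FALSE) {
  frames <- seq$frames
  n <- length(frames)
  if (n == 0) stop_input("empty frame sequence")
  detector <- detector %||% (
    if (!is.null(seq$face_box)) detector_stub(seq$face_box)
    else detector_bright_patch()
  )
  layout <- NULL
  vals <- matrix(NA_real_, n, 3)
  npx <- integer(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    if (is.null(layout) || (i - 1) %% redetect_every == 0) {
      det_frame <- if (enhance) enhance_for_detection(frames[[i]])
                   else frames[[i]]
      box <- detect_face(det_frame, detector)
      if (!is.null(box)) {
        layout <- layout_rois(box, geometry, tiles, source_frame_index = i)
      } else {
        flagged[i] <- TRUE
      }
    }
    if (is.null(layout)) next # still no face ever seen
    for (ch in c("r", "g", "b")) {
      sa <- spatial_average(frames[[i]], layout, ch)
      vals[i, match(ch, c("r", "g", "b"))] <- sa$mean
      npx[i] <- sa$n_pixels
    }
  }
  if (all(is.na(vals[, 2]))) stop_input("no face detected in any frame")
  # frames before the first successful detection carry the first layout back
  first_ok <- which(!is.na(vals[, 2]))[1]
  if (first_ok > 1) {
    for (i in seq_len(first_ok - 1)) {
      for (ch in 1:3) vals[i, ch] <- vals[first_ok, ch]
      npx[i] <- npx[first_ok]
      flagged[i] <- TRUE
    }
  }
  raw_trace(time = seq$timestamps, r = vals[, 1], g = vals[, 2],
            b = vals[, 3], fps = seq$fps, n_pixels = npx, flagged = flagged)
}

#' Read an image-sequence directory as frames
#'
#' Frames are PNG files read in lexicographic order; the frame rate must be
#' supplied (or is taken from a `fps.txt` file in the directory).
#'
#' @param path Directory of numbered `.png` frames.
#' @param fps Frames per second.
#' @return A `frame_sequence`.
#' @export
read_frames_dir <- function(path, fps = NULL) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_input("reading PNG frames requires the `png` package")
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop_input(sprintf("no PNG frames under %s", path))
  if (is.null(fps)) {
    fps_file <- file.path(path, "fps.txt")
    if (file.exists(fps_file)) fps <- as.numeric(readLines(fps_file, n = 1))
  }
  check_number(fps, "fps", lower = 1e-6)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3 && dim(img)[3] >= 3) img[, , 1:3] else img
  })
  structure(list(frames = frames, fps = fps,
                 timestamps = (seq_along(frames) - 1) / fps),
            class = "frame_sequence")
}

#' Read a PURE-style session (frame folder + JSON ground truth)
#'
#' Expects a directory of PNG frames and a JSON file whose `/FullPackage`
#' entries carry `Timestamp` (ns) and `Value.pulseRate`. Returns the frames
#' plus the pulse-rate reference resampled to seconds from session start.
#'
#' @param frames_dir Directory with the session's image frames.
#' @param json_path Path to the session JSON.
#' @param fps Frame rate of the recording (PURE uses 30 fps).
#' @return List `sequence` (a `frame_sequence`) and `reference`
#'   (tibble `time`, `hr_bpm`).
#' @export
read_pure_session <- function(frames_dir, json_path, fps = 30) {
  meta <- jsonlite::read_json(json_path)
  pkg <- meta[["/FullPackage"]] %||% meta[["FullPackage"]]
  if (is.null(pkg)) stop_input("JSON has no /FullPackage pulse entries")
  ts <- vapply(pkg, function(e) as.numeric(e$Timestamp), numeric(1))
  hr <- vapply(pkg, function(e) as.numeric(e$Value$pulseRate), numeric(1))
  reference <- tibble::tibble(time = (ts - ts[1]) / 1e9, hr_bpm = hr)
  list(sequence = read_frames_dir(frames_dir, fps), reference = reference)
}
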