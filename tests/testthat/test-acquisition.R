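make_frame <- function(h = 64, w = 64, bg = 0.2) {
  array(bg, dim = c(h, w, 3))
}

test_that("stub detection passes boxes through and clips to frame bounds", {
  frame <- make_frame()
  box <- c(x = 10, y = 8, w = 30, h = 40)
  expect_equal(detect_face(frame, detector_stub(box)), box)
  # a detector reporting a box sticking out is clipped: interval intersection
  out_box <- c(x = 50, y = 50, w = 30, h = 30)
  clipped <- detect_face(frame, detector_stub(out_box))
  expect_equal(clipped, c(x = 50, y = 50, w = 14, h = 14))
  expect_error(detect_face(array(0, c(2, 2, 2, 2)), detector_stub(box)),
               class = "rppg_input_error")
})

test_that("the luminance detector finds a bright patch and rejects blank frames", {
  frame <- make_frame()
  frame[20:50, 15:45, ] <- 0.7
  box <- detect_face(frame, detector_bright_patch())
  expect_equal(unname(box), c(14, 19, 31, 31))
  expect_null(detect_face(make_frame(), detector_bright_patch()))
})

test_that("detection enhancement never touches the trace values", {
  vid <- generate_video(clean_spec(duration = 3))
  tr_plain <- extract_trace(vid, enhance = FALSE)
  tr_enh <- extract_trace(vid, enhance = TRUE)
  expect_identical(tr_plain$g, tr_enh$g)
  expect_identical(tr_plain$r, tr_enh$r)
})

test_that("enhancement output is grayscale, bounded, and stretches contrast", {
  flat <- make_frame(bg = 0.5)
  enh <- enhance_for_detection(flat)
  expect_true(all(abs(enh - enh[1, 1]) < 1e-9)) # nothing to enhance
  grad <- make_frame()
  ramp <- matrix(seq(0.4, 0.6, length.out = 64), 64, 64, byrow = TRUE)
  for (ch in 1:3) grad[, , ch] <- ramp
  enh2 <- enhance_for_detection(grad)
  expect_gte(diff(range(enh2)), diff(range(ramp)) - 1e-9)
  expect_true(all(enh2 >= 0 & enh2 <= 1))
})

test_that("ROI layout respects the face box and tiling geometry", {
  fb <- c(x = 0, y = 0, w = 100, h = 100)
  lay <- layout_rois(fb, tiles = 1)
  # forehead in the upper half, cheeks in the lower half
  expect_lte(lay$regions$forehead[["y"]] + lay$regions$forehead[["h"]], 50)
  expect_gte(lay$regions$left_cheek[["y"]], 50)
  expect_gte(lay$regions$right_cheek[["y"]], 50)
  for (r in lay$regions) {
    expect_gte(r[["x"]], 0)
    expect_lte(r[["x"]] + r[["w"]], 100)
    expect_gt(r[["w"]] * r[["h"]], 0)
  }
  # tiles = 1 keeps regions whole
  expect_equal(lay$sub_rois$forehead[[1]], lay$regions$forehead)
  expect_error(layout_rois(c(x = 0, y = 0, w = 3, h = 3)),
               class = "rppg_input_error")
})

test_that("2x2 tiling covers a region exactly with disjoint tiles", {
  region <- c(x = 10, y = 20, w = 40, h = 40)
  tiles <- tile_region(region, 2)
  expect_length(tiles, 4)
  # exhaustive pixel membership: each region pixel in exactly one tile
  cover <- matrix(0L, 40, 40)
  for (tl in tiles) {
    rows <- (tl[["y"]] - 20 + 1):(tl[["y"]] - 20 + tl[["h"]])
    cols <- (tl[["x"]] - 10 + 1):(tl[["x"]] - 10 + tl[["w"]])
    cover[rows, cols] <- cover[rows, cols] + 1L
  }
  expect_true(all(cover == 1L))
  expect_true(all(vapply(tiles, function(t) t[["w"]] == 20 && t[["h"]] == 20,
                         logical(1))))
})

test_that("spatial averaging equals the brute-force mean and is tiling-invariant", {
  set.seed(71)
  frame <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  fb <- c(x = 4, y = 4, w = 48, h = 48)
  means <- vapply(c(1, 2, 4), function(k) {
    lay <- layout_rois(fb, tiles = k)
    spatial_average(frame, lay, "g")$mean
  }, numeric(1))
  expect_equal(means[1], means[2], tolerance = 1e-12)
  expect_equal(means[1], means[3], tolerance = 1e-12)
  # brute-force double loop over the union of tile pixels
  lay <- layout_rois(fb, tiles = 2)
  acc <- 0
  n <- 0
  for (region in lay$sub_rois) for (tl in region) {
    for (i in seq_len(tl[["h"]])) for (j in seq_len(tl[["w"]])) {
      acc <- acc + frame[tl[["y"]] + i, tl[["x"]] + j, 2]
      n <- n + 1
    }
  }
  expect_equal(spatial_average(frame, lay, "g")$mean, acc / n)
  expect_equal(spatial_average(frame, lay, "g")$n_pixels, n)
  # uniform field and tiny arithmetic case
  frame[, , 2] <- 0.5
  expect_equal(spatial_average(frame, lay, "g")$mean, 0.5)
})

test_that("extract_trace recovers constant and modulated skin values", {
  vid <- generate_video(clean_spec(duration = 5))
  tr <- extract_trace(vid)
  expect_s3_class(tr, "rppg_trace")
  expect_equal(nrow(tr), length(vid$frames))
  # injected green modulation is recovered up to affine scaling
  expect_gt(cor(tr$g, vid$trace$g), 0.99)
})

test_that("failed detections carry the last layout forward and are flagged", {
  vid <- generate_video(clean_spec(duration = 3))
  calls <- 0
  flaky <- function(frame) {
    calls <<- calls + 1
    if (calls %in% 2:3) NULL else vid$face_box
  }
  tr <- extract_trace(vid, detector = flaky, redetect_every = 10)
  expect_equal(nrow(tr), 90)
  expect_true(all(is.finite(tr$g)))
  expect_true(any(tr$flagged))
  # a detector that never fires is an extraction error
  expect_error(extract_trace(vid, detector = function(f) NULL),
               class = "rppg_input_error")
})
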