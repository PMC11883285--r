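# Detection: median background, segmentation, object measurement, fly
# detections with multi-fly blob splitting.

#' Compute the median background of a vial video
#'
#' Per-pixel median over all frames. Because a fly occupies any one pixel in
#' well under half the frames of a trial, the median recovers the clean
#' backlit field; even frame counts use the midpoint mean of the two middle
#' order statistics.
#'
#' @param stack a [FrameStack] with at least 3 frames.
#' @return numeric matrix of the same frame dimensions, values in `[0, 1]`.
#' @export
computeBackground <- function(stack) {
  if (nFrames(stack) < 3L) {
    stop("background estimation needs at least 3 frames", call. = FALSE)
  }
  median_stack(stack@frames)
}

#' Segment moving objects in one frame
#'
#' Flies are dark on a bright backlit field, so the frame is subtracted from
#' the background and thresholded: mask = 1 where
#' `background - frame > diffThreshold` (differences at or below the
#' threshold are set to 0).
#'
#' @param frame,background numeric matrices of identical shape, `[0, 1]`.
#' @param diffThreshold intensity difference threshold (default 0.06).
#' @return integer 0/1 matrix.
#' @export
segmentFrame <- function(frame, background, diffThreshold = 0.06) {
  if (!identical(dim(frame), dim(background))) {
    stop("frame and background dimensions differ", call. = FALSE)
  }
  # strict inequality with a guard against floating-point representation of
  # the threshold: a difference exactly at diffThreshold stays background
  mask <- (background - frame) - diffThreshold > 1e-12
  storage.mode(mask) <- "integer"
  mask
}

#' Measure connected components of a binary mask
#'
#' Labels connected components (8-connected by default) and measures each:
#' centroid (mean of member pixel coordinates, 0-based), pixel area, and
#' major/minor axis lengths of the ellipse with equal second central moments.
#' Moments include the 1/12 pixel-bin variance correction so 1-px-wide
#' components get a positive minor axis.
#'
#' @param mask integer/logical binary matrix.
#' @param connectivity 8 (default) or 4.
#' @return data.frame with columns `x_px`, `y_px`, `area_px`,
#'   `major_axis_px`, `minor_axis_px`; zero rows for an empty mask.
#' @export
extractObjects <- function(mask, connectivity = 8) {
  storage.mode(mask) <- "integer"
  lab <- cc_label(mask, as.integer(connectivity))
  n <- max(lab)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = integer(0), major_axis_px = numeric(0),
                      minor_axis_px = numeric(0))
  if (n == 0L) return(empty)
  idx <- which(lab > 0L)
  l <- lab[idx]
  # 0-based pixel coordinates: x along columns, y along rows
  yy <- (idx - 1L) %% nrow(mask)
  xx <- (idx - 1L) %/% nrow(mask)
  area <- tabulate(l, n)
  sx <- tapply(xx, l, sum); sy <- tapply(yy, l, sum)
  cx <- as.numeric(sx) / area
  cy <- as.numeric(sy) / area
  dx <- xx - cx[l]; dy <- yy - cy[l]
  mxx <- as.numeric(tapply(dx * dx, l, sum)) / area + 1 / 12
  myy <- as.numeric(tapply(dy * dy, l, sum)) / area + 1 / 12
  mxy <- as.numeric(tapply(dx * dy, l, sum)) / area
  tr <- mxx + myy
  det <- mxx * myy - mxy * mxy
  disc <- sqrt(pmax(0, tr * tr / 4 - det))
  e1 <- tr / 2 + disc
  e2 <- pmax(0, tr / 2 - disc)
  data.frame(x_px = cx, y_px = cy, area_px = as.integer(area),
             major_axis_px = 4 * sqrt(e1), minor_axis_px = 4 * sqrt(e2))
}

#' Turn measured objects into individual-fly detections
#'
#' Applies the calibration classification: noise objects are dropped, a
#' single-fly object yields one detection, and a multi-fly blob is split into
#' `k = ceiling(area / areaSingleMaxPx)` clone detections sharing the blob
#' centroid, so that every detection represents an individual fly. An exact
#' integer quotient stays at that integer (no phantom extra fly).
#'
#' @param objects data.frame from [extractObjects()].
#' @param thresholds a [DetectionThresholds].
#' @return data.frame with columns `x_px`, `y_px`, `multiplicity` (the blob's
#'   fly count, repeated on each clone row).
#' @export
detectFlies <- function(objects, thresholds) {
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      multiplicity = integer(0))
  if (nrow(objects) == 0L) return(empty)
  cls <- classifyObject(objects$area_px, objects$minor_axis_px,
                        objects$major_axis_px, thresholds)
  keep <- objects[cls != "noise", , drop = FALSE]
  cls <- cls[cls != "noise"]
  if (nrow(keep) == 0L) return(empty)
  k <- ifelse(cls == "single", 1L,
              as.integer(ceiling(round(keep$area_px / thresholds@areaSingleMaxPx,
                                       9))))
  data.frame(x_px = rep(keep$x_px, k), y_px = rep(keep$y_px, k),
             multiplicity = rep(k, k))
}

#' Run detection over every frame of a vial video
#'
#' Computes the median background once, then segments and measures each frame
#' independently (no temporal smoothing) and converts measured objects to
#' individual-fly detections.
#'
#' @param stack a vial-cropped [FrameStack].
#' @param thresholds a [DetectionThresholds].
#' @param config a `GeotaxisConfig` (supplies `diff_threshold` and
#'   `connectivity`).
#' @return list with `detections` (one data.frame per frame) and
#'   `background` (the median frame).
#' @export
detectVideo <- function(stack, thresholds, config = geotaxisConfig()) {
  bg <- computeBackground(stack)
  n <- nFrames(stack)
  dets <- vector("list", n)
  for (i in seq_len(n)) {
    mask <- segmentFrame(stack@frames[, , i], bg, config$diff_threshold)
    obj <- extractObjects(mask, config$connectivity)
    dets[[i]] <- detectFlies(obj, thresholds)
  }
  list(detections = dets, background = bg)
}
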