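#' Number of frames in an object
#' @param x a FrameStack or CoordinateMatrix
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of flies in an object
#' @param x a CoordinateMatrix or GroundTruth
#' @return integer fly count
#' @export
setGeneric("nFlies", function(x) standardGeneric("nFlies"))

#' Acquisition frame rate
#' @param x a FrameStack
#' @return frames per second
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' Extract a single frame
#' @param x a FrameStack
#' @param i frame index (1-based)
#' @return numeric matrix
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Per-fly coordinate matrices
#'
#' Returns the positions held by a [CoordinateMatrix] or [GroundTruth] as a
#' list with numeric matrices `x` and `y` (`nFlies x nFrames`, 0-based pixels).
#' @param x the object
#' @return list with elements `x` and `y`
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))

#' Labeled calibration measurements
#' @param x a CalibrationTable
#' @return data.frame of labeled object measurements
#' @export
setGeneric("calibrationObjects", function(x) standardGeneric("calibrationObjects"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[3])
#' @rdname nFrames
#' @export
setMethod("nFrames", "CoordinateMatrix", function(x) ncol(x@x))
#' @rdname nFrames
#' @export
setMethod("nFrames", "GroundTruth", function(x) ncol(x@x))

#' @rdname nFlies
#' @export
setMethod("nFlies", "CoordinateMatrix", function(x) nrow(x@x))
#' @rdname nFlies
#' @export
setMethod("nFlies", "GroundTruth", function(x) nrow(x@x))

#' @rdname frameRate
#' @export
setMethod("frameRate", "FrameStack", function(x) x@frameRate)

#' @rdname getFrame
#' @export
setMethod("getFrame", "FrameStack", function(x, i) x@frames[, , i])

#' @rdname coordinates
#' @export
setMethod("coordinates", "CoordinateMatrix", function(x) list(x = x@x, y = x@y))
#' @rdname coordinates
#' @export
setMethod("coordinates", "GroundTruth", function(x) list(x = x@x, y = x@y))

#' @rdname calibrationObjects
#' @export
setMethod("calibrationObjects", "CalibrationTable", function(x) x@objects)

#' Visibility matrix of tracked coordinates
#'
#' TRUE where the saved coordinate came from an assigned detection, FALSE
#' where the track coasted on its last known position or was bottom-seeded.
#' @param x a CoordinateMatrix
#' @return logical matrix, `nFlies x nFrames`
#' @export
setGeneric("visibility", function(x) standardGeneric("visibility"))
#' @rdname visibility
#' @export
setMethod("visibility", "CoordinateMatrix", function(x) x@visible)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat("FrameStack:", d[3], "frames of", d[1], "x", d[2], "px at",
      object@frameRate, "Hz\n")
})

setMethod("show", "CalibrationTable", function(object) {
  tab <- table(factor(object@objects$label,
                      levels = c("single", "multi", "noise")))
  cat("CalibrationTable:", nrow(object@objects), "labeled objects (",
      "single:", tab[["single"]], " multi:", tab[["multi"]],
      " noise:", tab[["noise"]], ")\n")
})

setMethod("show", "DetectionThresholds", function(object) {
  cat("DetectionThresholds\n")
  cat(sprintf("  area: noise < %.2f <= single <= %.2f < multi <= %.2f px^2\n",
              object@areaMinPx, object@areaSingleMaxPx, object@areaMultiMaxPx))
  cat(sprintf("  minor/major ratio: single [%.3f, %.3f], multi [%.3f, %.3f]\n",
              object@ratioSingle[1], object@ratioSingle[2],
              object@ratioMulti[1], object@ratioMulti[2]))
})

setMethod("show", "CoordinateMatrix", function(object) {
  cat("CoordinateMatrix: vial", object@vialId, "-", nrow(object@x), "flies x",
      ncol(object@x), "frames;",
      sprintf("%.1f%% coordinates from detections\n", 100 * mean(object@visible)))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@x), "flies x", ncol(object@x), "frames;",
      nrow(object@drops), "planted drops\n")
})

setMethod("show", "AccuracyReport", function(object) {
  cat("AccuracyReport (", object@nFlies, "flies x", object@nFrames, "frames )\n")
  cat(sprintf("  fraction correct (tol %.0f px): %.4f\n", object@tolPx,
              object@fractionCorrect))
  cat(sprintf("  mean localization error (correct frames): %.3f px\n",
              object@meanErrorPx))
  cat(sprintf("  identity-switch frame fraction: %.4f\n", object@switchFraction))
  cat(sprintf("  missing-coordinate fraction: %.4f\n", object@missingFraction))
  cat(sprintf("  large-jump fraction (top 1%%/vial length): %.4f\n",
              object@largeJumpFraction))
})
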