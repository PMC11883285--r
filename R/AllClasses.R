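#' @import methods
#' @importFrom stats cor quantile rnorm runif rgeom dist sd setNames
#' @importFrom utils read.csv write.csv head
#' @useDynLib geotrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' FrameStack: an ordered grayscale image sequence
#'
#' Container for a vial video held in memory as an `H x W x N` numeric array
#' with pixel values normalized to `[0, 1]`, together with the acquisition
#' frame rate. Row index is the image y axis (downward), column index the
#' x axis (rightward); pixel indices are 0-based in all coordinate output.
#'
#' @slot frames numeric array, `H x W x N`, values in `[0, 1]`.
#' @slot frameRate positive numeric, frames per second.
#' @export
setClass("FrameStack",
  representation(frames = "array", frameRate = "numeric"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 3L) return("frames must be an H x W x N array")
    if (d[3] < 1L) return("frames must contain at least one frame")
    if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
        object@frameRate <= 0) {
      return("frameRate must be a single positive number")
    }
    rng <- range(object@frames)
    if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1) {
      return("pixel values must lie in [0, 1]")
    }
    TRUE
  }
)

#' CalibrationTable: labeled example objects
#'
#' Measurements (pixel area, major/minor axis lengths) of example objects
#' labeled as a single fly, multiple flies, or noise. The table is the
#' file-based replacement for interactive click-classification: it captures
#' the size and shape distributions of the flies as imaged, from which
#' [deriveThresholds()] computes the detection acceptance thresholds.
#'
#' @slot objects data.frame with columns `area_px`, `major_axis_px`,
#'   `minor_axis_px`, `label` (one of `"single"`, `"multi"`, `"noise"`).
#' @export
setClass("CalibrationTable",
  representation(objects = "data.frame"),
  validity = function(object) {
    df <- object@objects
    need <- c("area_px", "major_axis_px", "minor_axis_px", "label")
    if (!all(need %in% names(df))) {
      return(paste("objects must have columns:", paste(need, collapse = ", ")))
    }
    if (nrow(df) == 0L) return("calibration table is empty")
    bad <- setdiff(unique(df$label), c("single", "multi", "noise"))
    if (length(bad)) return(paste("unknown label:", bad[1]))
    if (any(df$area_px <= 0)) return("area_px must be positive")
    if (any(df$minor_axis_px > df$major_axis_px + 1e-9)) {
      return("minor_axis_px must not exceed major_axis_px")
    }
    TRUE
  }
)

#' DetectionThresholds: size/shape acceptance bounds
#'
#' Classification thresholds derived from a [CalibrationTable]. Objects with
#' area below `areaMinPx` (a low percentile of the single-fly areas, 16% by
#' default) or above `areaMultiMaxPx` are noise; areas up to `areaSingleMaxPx`
#' are single flies, larger ones multi-fly blobs. A candidate is demoted to
#' noise when its minor/major axis ratio falls outside the candidate class's
#' observed ratio interval.
#'
#' @slot areaMinPx numeric, lower area bound (px^2).
#' @slot areaSingleMaxPx numeric, largest single-fly area (px^2).
#' @slot areaMultiMaxPx numeric, largest multi-fly area (px^2).
#' @slot ratioSingle numeric length 2, closed minor/major ratio interval
#'   for single flies, subset of (0, 1].
#' @slot ratioMulti numeric length 2, ratio interval for multi-fly blobs.
#' @export
setClass("DetectionThresholds",
  representation(areaMinPx = "numeric", areaSingleMaxPx = "numeric",
                 areaMultiMaxPx = "numeric", ratioSingle = "numeric",
                 ratioMulti = "numeric"),
  validity = function(object) {
    if (!(object@areaMinPx < object@areaSingleMaxPx &&
          object@areaSingleMaxPx < object@areaMultiMaxPx)) {
      return("need areaMinPx < areaSingleMaxPx < areaMultiMaxPx")
    }
    for (nm in c("ratioSingle", "ratioMulti")) {
      r <- slot(object, nm)
      if (length(r) != 2L || r[1] > r[2] || r[1] <= 0 || r[2] > 1) {
        return(paste(nm, "must be an interval within (0, 1]"))
      }
    }
    TRUE
  }
)

#' CoordinateMatrix: finalized per-fly positions
#'
#' The end product of tracking one vial video: an `nFlies x nFrames` pair of
#' coordinate matrices in 0-based pixel units of the cropped region of
#' interest, plus a visibility matrix recording which coordinates came from an
#' actual detection (as opposed to coasting on last known coordinates or
#' bottom seeding of never-seen flies).
#'
#' @slot x,y numeric matrices, `nFlies x nFrames`, pixel coordinates.
#' @slot visible logical matrix of the same shape.
#' @slot vialId integer vial identifier.
#' @slot metadata list of provenance fields (video name, trial index, ...).
#' @export
setClass("CoordinateMatrix",
  representation(x = "matrix", y = "matrix", visible = "matrix",
                 vialId = "integer", metadata = "list"),
  validity = function(object) {
    dx <- dim(object@x)
    if (!identical(dx, dim(object@y)) || !identical(dx, dim(object@visible))) {
      return("x, y and visible must have identical dimensions")
    }
    if (dx[1] < 1L || dx[2] < 1L) return("need at least one fly and one frame")
    if (!all(is.finite(object@x)) || !all(is.finite(object@y))) {
      return("coordinates must be finite")
    }
    TRUE
  }
)

#' GroundTruth: simulated trajectories with planted events
#'
#' True per-fly, per-frame positions from the synthetic-video simulator, the
#' behavioral state occupied at each frame, and the planted slip/fall events.
#' Positions are 0-based pixels in the simulated region of interest (image
#' convention, y downward).
#'
#' @slot x,y numeric matrices, `nFlies x nFrames`, true pixel positions.
#' @slot state character matrix of the same shape with values in
#'   `climb`, `pause`, `slip`, `fall`.
#' @slot drops data.frame of planted events: `fly`, `frame` (the 0-based
#'   index of the frame after the drop), `kind`, `dropMm`, `preDropHeightMm`.
#' @slot params the `SimParams` list that produced the trajectories.
#' @export
setClass("GroundTruth",
  representation(x = "matrix", y = "matrix", state = "matrix",
                 drops = "data.frame", params = "list"),
  validity = function(object) {
    if (!identical(dim(object@x), dim(object@y))) return("x/y dims differ")
    if (!identical(dim(object@x), dim(object@state))) return("state dims differ")
    ok <- object@state %in% c("climb", "pause", "slip", "fall")
    if (!all(ok)) return("state values must be climb/pause/slip/fall")
    TRUE
  }
)

#' AccuracyReport: tracking scored against ground truth
#'
#' Per-video accuracy summary from [evaluateTracking()]. Tracked positions are
#' matched to true positions frame by frame with a minimum-total-distance
#' assignment (identity-agnostic), so the headline fraction measures single-fly
#' localization rather than label persistence; identity switches are reported
#' separately as the fraction of frame transitions at which the matching
#' permutation changes.
#'
#' @slot fractionCorrect fraction of (fly, frame) positions within tolerance.
#' @slot meanErrorPx mean matched distance over correct positions (px).
#' @slot errorsPx numeric vector of all matched distances (px).
#' @slot switchFraction fraction of frame transitions with a permutation change.
#' @slot missingFraction fraction of coordinates not backed by a detection.
#' @slot largeJumpFraction mean of each track's top-1% frame-to-frame
#'   displacements, normalized to the vial (ROI) height.
#' @slot tolPx tolerance used (px).
#' @slot nFlies,nFrames problem size.
#' @export
setClass("AccuracyReport",
  representation(fractionCorrect = "numeric", meanErrorPx = "numeric",
                 errorsPx = "numeric", switchFraction = "numeric",
                 missingFraction = "numeric", largeJumpFraction = "numeric",
                 tolPx = "numeric", nFlies = "integer", nFrames = "integer"),
  validity = function(object) {
    fr <- c(object@fractionCorrect, object@switchFraction,
            object@missingFraction)
    if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
    TRUE
  }
)
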