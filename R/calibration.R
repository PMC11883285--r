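# Calibration: labeled object measurements -> detection thresholds.

#' Build a calibration table from a labeled CSV
#'
#' Reads size/shape measurements of example objects labeled `single`, `multi`
#' or `noise` (columns `area_px`, `major_axis_px`, `minor_axis_px`, `label`).
#' Errors name the first offending row for unknown labels or non-positive
#' areas.
#'
#' @param path CSV file of labeled measurements.
#' @return a [CalibrationTable].
#' @export
buildCalibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("area_px", "major_axis_px", "minor_axis_px", "label")
  if (!all(need %in% names(df))) {
    stop("calibration CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("calibration CSV is empty; cannot derive thresholds", call. = FALSE)
  }
  bad <- which(!df$label %in% c("single", "multi", "noise"))
  if (length(bad)) {
    stop("row ", bad[1], ": unknown label '", df$label[bad[1]],
         "' (expected single/multi/noise)", call. = FALSE)
  }
  bad <- which(df$area_px <= 0)
  if (length(bad)) {
    stop("row ", bad[1], ": area_px must be positive", call. = FALSE)
  }
  calibrationTable(df)
}

#' Construct a CalibrationTable from a data.frame
#' @param objects data.frame with columns `area_px`, `major_axis_px`,
#'   `minor_axis_px`, `label`.
#' @return a [CalibrationTable].
#' @export
calibrationTable <- function(objects) {
  new("CalibrationTable", objects = objects[, c("area_px", "major_axis_px",
                                                "minor_axis_px", "label")])
}

#' Derive detection thresholds from calibration data
#'
#' Computes the area and axis-ratio acceptance bounds used to discriminate
#' flies from noise. The lower area bound is the `areaPercentile` quantile
#' (default the 16th percentile) of the single-fly areas, using the standard
#' linear interpolation between order statistics ([stats::quantile()] type 7);
#' the single/multi boundary is the maximum single-fly area, and anything
#' above the maximum multi-fly area is noise. Axis-ratio intervals per class
#' are the observed `[min, max]` of minor/major ratios, optionally trimmed
#' symmetrically by `ratioTrim` (a quantile fraction; 0 keeps the full range).
#'
#' @param table a [CalibrationTable] with at least one `single` and one
#'   `multi` object.
#' @param areaPercentile lower-tail fraction of single-fly areas classed as
#'   noise (default 0.16).
#' @param ratioTrim symmetric trim fraction for the ratio intervals.
#' @return a [DetectionThresholds]; errors if a class is missing or the
#'   derived bounds are degenerate (e.g. all single areas equal).
#' @export
deriveThresholds <- function(table, areaPercentile = 0.16, ratioTrim = 0) {
  df <- table@objects
  s <- df[df$label == "single", ]
  m <- df[df$label == "multi", ]
  if (nrow(s) == 0L) stop("calibration has no single-fly objects", call. = FALSE)
  if (nrow(m) == 0L) stop("calibration has no multi-fly objects", call. = FALSE)
  areaMin <- unname(quantile(s$area_px, areaPercentile, type = 7))
  areaSingleMax <- max(s$area_px)
  areaMultiMax <- max(m$area_px)
  if (!(areaMin < areaSingleMax && areaSingleMax < areaMultiMax)) {
    stop("degenerate calibration: need areaMin < max(single) < max(multi) ",
         sprintf("(got %.2f, %.2f, %.2f)", areaMin, areaSingleMax, areaMultiMax),
         call. = FALSE)
  }
  interval <- function(x) {
    r <- unname(quantile(x, c(ratioTrim, 1 - ratioTrim), type = 7))
    if (r[1] <= 0 || r[2] > 1 || r[1] > r[2]) {
      stop("axis ratios must lie in (0, 1]", call. = FALSE)
    }
    r
  }
  new("DetectionThresholds",
      areaMinPx = areaMin, areaSingleMaxPx = areaSingleMax,
      areaMultiMaxPx = areaMultiMax,
      ratioSingle = interval(s$minor_axis_px / s$major_axis_px),
      ratioMulti = interval(m$minor_axis_px / m$major_axis_px))
}

#' Classify a detected object as single fly, multiple flies, or noise
#'
#' Total, piecewise-constant classification rule. Area below `areaMinPx` or
#' above `areaMultiMaxPx` is noise; otherwise the area picks the candidate
#' class (single up to and including `areaSingleMaxPx`, multi above), and the
#' candidate is demoted to noise if the minor/major axis ratio falls outside
#' that class's closed ratio interval. Boundary areas belong to the class
#' whose extremum they equal: `areaMinPx` and `areaSingleMaxPx` are single,
#' `areaMultiMaxPx` is multi.
#'
#' @param areaPx,minorAxisPx,majorAxisPx object measurements (vectorized).
#' @param thresholds a [DetectionThresholds].
#' @return character vector in `c("single", "multi", "noise")`.
#' @export
classifyObject <- function(areaPx, minorAxisPx, majorAxisPx, thresholds) {
  t <- thresholds
  ratio <- minorAxisPx / majorAxisPx
  cls <- ifelse(areaPx < t@areaMinPx | areaPx > t@areaMultiMaxPx, "noise",
                ifelse(areaPx <= t@areaSingleMaxPx, "single", "multi"))
  inInt <- function(x, int) x >= int[1] & x <= int[2]
  demote <- (cls == "single" & !inInt(ratio, t@ratioSingle)) |
            (cls == "multi" & !inInt(ratio, t@ratioMulti))
  cls[demote] <- "noise"
  cls
}

#' Serialize detection thresholds to JSON
#'
#' Thresholds are written as a flat JSON object so a calibration can be
#' reused across recursive video-processing runs.
#'
#' @param thresholds a [DetectionThresholds].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeThresholds <- function(thresholds, path) {
  jsonlite::write_json(list(
    area_min_px = thresholds@areaMinPx,
    area_single_max_px = thresholds@areaSingleMaxPx,
    area_multi_max_px = thresholds@areaMultiMaxPx,
    ratio_single = thresholds@ratioSingle,
    ratio_multi = thresholds@ratioMulti
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read detection thresholds from JSON
#' @param path JSON file written by [writeThresholds()].
#' @return a [DetectionThresholds].
#' @export
readThresholds <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DetectionThresholds",
      areaMinPx = j$area_min_px, areaSingleMaxPx = j$area_single_max_px,
      areaMultiMaxPx = j$area_multi_max_px,
      ratioSingle = j$ratio_single, ratioMulti = j$ratio_multi)
}
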