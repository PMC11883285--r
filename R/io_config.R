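# Run configuration, video/frame reading, ROI cropping, coordinate I/O.

.configDefaults <- function() {
  list(
    frame_rate_hz       = 30,
    n_flies             = 7L,
    con                 = 11,
    diff_threshold      = 0.06,
    displacement_gate_mm = 4,
    slip_min_mm         = 4.5,
    slip_max_mm         = 12,
    px_per_mm           = 4.85,
    vial_height_mm      = 140,
    target_heights_mm   = c(140 / 3, 70, 140),
    n_bootstrap         = 1000L,
    rng_seed            = 0L,
    cost_rule           = "min",
    connectivity        = 8L,
    area_percentile     = 0.16,
    ratio_trim          = 0,
    measurement_noise_px = 1,
    process_noise_px    = 1,
    init_velocity_var   = 100,
    angle_tol_deg       = 1e-6,
    max_invisible_frames = 3L,
    rois                = NULL
  )
}

.validateConfig <- function(cfg) {
  stopPos <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) < 1L || any(!is.finite(v)) || any(v <= 0)) {
      stop("config key '", key, "' must be positive", call. = FALSE)
    }
  }
  for (k in c("frame_rate_hz", "n_flies", "displacement_gate_mm",
              "slip_min_mm", "slip_max_mm", "px_per_mm", "vial_height_mm",
              "target_heights_mm", "n_bootstrap")) stopPos(k)
  if (!is.numeric(cfg$con) || cfg$con < 0) {
    stop("config key 'con' must be non-negative", call. = FALSE)
  }
  if (cfg$diff_threshold <= 0 || cfg$diff_threshold >= 1) {
    stop("config key 'diff_threshold' must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$slip_min_mm >= cfg$slip_max_mm) {
    stop("config keys 'slip_min_mm'/'slip_max_mm': need slip_min_mm < slip_max_mm",
         call. = FALSE)
  }
  if (any(cfg$target_heights_mm > cfg$vial_height_mm)) {
    stop("config key 'target_heights_mm' must not exceed vial_height_mm",
         call. = FALSE)
  }
  if (!cfg$cost_rule %in% c("min", "mean", "pred")) {
    stop("config key 'cost_rule' must be one of min/mean/pred", call. = FALSE)
  }
  if (!cfg$connectivity %in% c(4L, 8L)) {
    stop("config key 'connectivity' must be 4 or 8", call. = FALSE)
  }
  if (!is.null(cfg$rois)) .validateRois(cfg$rois)
  cfg$n_flies <- as.integer(cfg$n_flies)
  cfg$n_bootstrap <- as.integer(cfg$n_bootstrap)
  cfg$connectivity <- as.integer(cfg$connectivity)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  class(cfg) <- "GeotaxisConfig"
  cfg
}

.validateRois <- function(rois) {
  need <- c("vial_id", "x0", "y0", "width", "height")
  if (!is.data.frame(rois) || !all(need %in% names(rois))) {
    stop("rois must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(rois$width <= 0) || any(rois$height <= 0)) {
    stop("ROI width and height must be positive", call. = FALSE)
  }
  key <- paste(rois$x0, rois$y0, rois$width, rois$height)
  if (anyDuplicated(key)) stop("ROIs must be pairwise non-identical", call. = FALSE)
  invisible(rois)
}

#' Build a run configuration
#'
#' Assembles the tracking/analytics configuration, filling defaults for
#' unsupplied keys. Defaults encode the platform's standard operating point:
#' 30 Hz acquisition, up to 7 flies per vial, cost of non-assignment (CON) 11,
#' background-difference threshold 0.06 on `[0, 1]` intensities, a 4 mm
#' frame-to-frame displacement gate, slip bounds 4.5-12 mm, a 140 mm vial with
#' climbing targets at 1/3, 1/2 and full height, and a pixel scale of
#' 4.85 px/mm (9.7 px ~ 2 mm).
#'
#' @param ... configuration keys to override (snake_case as in the JSON
#'   schema, e.g. `con = 9`, `n_flies = 5`).
#' @return a validated `GeotaxisConfig` list.
#' @examples
#' cfg <- geotaxisConfig()
#' cfg$con
#' @export
geotaxisConfig <- function(...) {
  cfg <- .configDefaults()
  user <- list(...)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config key: '", bad[1], "'", call. = FALSE)
  cfg[names(user)] <- user
  .validateConfig(cfg)
}

#' Load a run configuration from JSON
#'
#' Reads a JSON file holding any subset of the configuration keys plus an
#' optional `"rois"` array of `{vial_id, x0, y0, width, height}` records.
#' Absent keys take defaults; unknown keys and invariant violations raise an
#' error naming the offending key.
#'
#' @param path path to the JSON configuration file.
#' @return a validated `GeotaxisConfig` list.
#' @seealso [geotaxisConfig()]
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) && is.null(names(raw))) {
    stop("config JSON must be an object", call. = FALSE)
  }
  if (!is.null(raw$rois)) {
    raw$rois <- as.data.frame(raw$rois)
  }
  do.call(geotaxisConfig, raw)
}

#' @export
print.GeotaxisConfig <- function(x, ...) {
  cat("GeotaxisConfig\n")
  scalars <- x[!vapply(x, is.null, logical(1))]
  scalars$rois <- NULL
  for (k in names(scalars)) {
    cat(sprintf("  %-22s %s\n", k, paste(format(scalars[[k]]), collapse = " ")))
  }
  if (!is.null(x$rois)) cat("  rois:", nrow(x$rois), "vials\n")
  invisible(x)
}

#' Construct a FrameStack from an array or list of matrices
#'
#' @param frames an `H x W x N` array or a list of equally sized matrices with
#'   values in `[0, 1]`.
#' @param frameRate frames per second.
#' @return a [FrameStack].
#' @export
frameStack <- function(frames, frameRate = 30) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
      stop("all frames must share identical dimensions", call. = FALSE)
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(d, length(frames)))
  }
  new("FrameStack", frames = frames, frameRate = frameRate)
}

.toGray <- function(img) {
  if (length(dim(img)) == 3L) {
    # color planes collapsed by channel mean (alpha, if present, ignored)
    nc <- min(dim(img)[3], 3L)
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  img
}

#' Read a vial video as a FrameStack
#'
#' Accepts a directory of lexicographically ordered PNG or TIFF frames.
#' Frames are converted to grayscale (channel mean for color input) and
#' normalized to `[0, 1]` whatever the source bit depth. MP4/AVI containers
#' are not decoded in-process; extract frames first (e.g.
#' `ffmpeg -i run.mp4 frames/f%05d.png`) and point `readVideo()` at the
#' directory.
#'
#' @param path directory containing `*.png`/`*.tif(f)` frames.
#' @param frameRate frames per second of the recording (default 30).
#' @return a [FrameStack]; errors on empty input or a single frame.
#' @export
readVideo <- function(path, frameRate = 30) {
  if (!file.exists(path)) stop("no such file or directory: ", path, call. = FALSE)
  if (!dir.exists(path)) {
    if (grepl("\\.(mp4|avi)$", path, ignore.case = TRUE)) {
      stop("video containers are not decoded in-process; extract frames to a ",
           "PNG/TIFF directory and pass that directory", call. = FALSE)
    }
    stop("unreadable video source: ", path, call. = FALSE)
  }
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no PNG/TIFF frames found in ", path, call. = FALSE)
  if (length(files) == 1L) stop("a video needs more than one frame", call. = FALSE)
  readOne <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      tiff::readTIFF(f)
    }
    .toGray(img)
  }
  frames <- lapply(files, readOne)
  frameStack(frames, frameRate = frameRate)
}

#' Crop a FrameStack to a rectangular region of interest
#'
#' The ROI is a half-open rectangle in full-frame pixel coordinates with
#' 0-based origin `(x0, y0)` at its top-left corner; cropping preserves the
#' frame count and yields `height x width` frames.
#'
#' @param stack a [FrameStack].
#' @param roi list or one-row data.frame with `x0`, `y0`, `width`, `height`.
#' @return the cropped [FrameStack].
#' @export
cropRoi <- function(stack, roi) {
  d <- dim(stack@frames)
  x0 <- roi$x0; y0 <- roi$y0; w <- roi$width; h <- roi$height
  if (w <= 0 || h <= 0) stop("ROI width and height must be positive", call. = FALSE)
  if (x0 < 0 || y0 < 0 || x0 + w > d[2] || y0 + h > d[1]) {
    stop("ROI exceeds frame bounds (", d[1], " x ", d[2], " px)", call. = FALSE)
  }
  new("FrameStack",
      frames = stack@frames[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), , drop = FALSE],
      frameRate = stack@frameRate)
}

#' Print a config ROI template for a given frame size
#'
#' Convenience helper for headless setups: emits a JSON `"rois"` stanza that
#' splits the frame into `nVials` equal vertical strips, to be pasted into the
#' run configuration and adjusted.
#'
#' @param frameHeight,frameWidth full-frame dimensions in pixels.
#' @param nVials number of vials across the frame.
#' @return the ROI data.frame, invisibly; the JSON is printed.
#' @export
roiTemplate <- function(frameHeight, frameWidth, nVials = 10) {
  w <- floor(frameWidth / nVials)
  rois <- data.frame(vial_id = seq_len(nVials), x0 = (seq_len(nVials) - 1L) * w,
                     y0 = 0L, width = w, height = frameHeight)
  cat(jsonlite::toJSON(list(rois = rois), pretty = TRUE, auto_unbox = TRUE), "\n")
  invisible(rois)
}

#' Construct a CoordinateMatrix
#'
#' @param x,y numeric `nFlies x nFrames` matrices, 0-based pixels.
#' @param visible logical matrix of the same shape (default all TRUE).
#' @param vialId integer vial identifier.
#' @param metadata provenance list.
#' @return a [CoordinateMatrix].
#' @export
coordinateMatrix <- function(x, y, visible = NULL, vialId = 1L,
                             metadata = list()) {
  if (is.null(visible)) visible <- matrix(TRUE, nrow(x), ncol(x))
  new("CoordinateMatrix", x = x, y = y, visible = visible,
      vialId = as.integer(vialId), metadata = metadata)
}

#' Write a coordinate matrix to CSV
#'
#' Long-format RFC 4180 CSV with header `frame_index,fly_id,x_px,y_px`;
#' frames are 0-based, fly ids 1-based, coordinates stored to 2 decimal
#' pixels. [readCoordinates()] restores an equal matrix at that precision.
#'
#' @param matrix a [CoordinateMatrix].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCoordinates <- function(matrix, path) {
  nfly <- nrow(matrix@x); nfr <- ncol(matrix@x)
  df <- data.frame(
    frame_index = rep(seq_len(nfr) - 1L, each = nfly),
    fly_id = rep(seq_len(nfly), times = nfr),
    x_px = round(as.vector(matrix@x), 2),
    y_px = round(as.vector(matrix@y), 2)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a coordinate matrix from CSV
#'
#' @param path CSV written by [writeCoordinates()].
#' @param vialId vial identifier to attach.
#' @return a [CoordinateMatrix]; errors name the first frame missing a fly.
#' @export
readCoordinates <- function(path, vialId = 1L) {
  df <- read.csv(path)
  need <- c("frame_index", "fly_id", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop("coordinate CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  frames <- sort(unique(df$frame_index))
  flies <- sort(unique(df$fly_id))
  nfr <- length(frames); nfly <- length(flies)
  if (!identical(frames, seq_len(nfr) - 1L) && !all(frames == seq_len(nfr) - 1)) {
    stop("frame_index must be contiguous from 0", call. = FALSE)
  }
  counts <- table(df$frame_index)
  bad <- names(counts)[counts != nfly]
  if (length(bad)) {
    stop("frame ", bad[1], " does not list every fly_id", call. = FALSE)
  }
  df <- df[order(df$frame_index, df$fly_id), ]
  if (nrow(df) != nfr * nfly || any(df$fly_id != rep(flies, times = nfr))) {
    stop("coordinate CSV has duplicate or missing (frame, fly) rows",
         call. = FALSE)
  }
  x <- matrix(df$x_px, nrow = nfly, ncol = nfr)
  y <- matrix(df$y_px, nrow = nfly, ncol = nfr)
  coordinateMatrix(x, y, vialId = vialId,
                   metadata = list(source = basename(path)))
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
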