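# Tracking: constant-velocity Kalman prediction, cost-of-non-assignment
# padded Hungarian matching, track management and finalization.

.kfF <- rbind(c(1, 0, 1, 0),
              c(0, 1, 0, 1),
              c(0, 0, 1, 0),
              c(0, 0, 0, 1))
.kfH <- rbind(c(1, 0, 0, 0),
              c(0, 1, 0, 0))

# White-acceleration process noise for unit frame step, per axis blocks.
.kfQ <- function(sigmaA) {
  q <- sigmaA^2
  rbind(c(q / 4, 0, q / 2, 0),
        c(0, q / 4, 0, q / 2),
        c(q / 2, 0, q, 0),
        c(0, q / 2, 0, q))
}

#' Create a Kalman track
#'
#' Initializes a constant-velocity Kalman filter at a detection. State is
#' `(x, y, vx, vy)` in px and px/frame; initial velocity is 0 with large
#' variance (`init_velocity_var`), so the first assignments are dominated by
#' position until the filter learns a velocity.
#'
#' @param id integer track identifier.
#' @param x,y initial position, 0-based pixels.
#' @param vx,vy initial velocity in px/frame (default 0).
#' @param config a `GeotaxisConfig` (Kalman noise settings).
#' @param frame 0-based index of the frame the track starts in.
#' @return a `KalmanTrack` list.
#' @export
newTrack <- function(id, x, y, vx = 0, vy = 0, config = geotaxisConfig(),
                     frame = 0L) {
  structure(list(
    id = as.integer(id),
    m = c(x, y, vx, vy),
    P = diag(c(1, 1, config$init_velocity_var, config$init_velocity_var)),
    lastKnown = c(x, y),
    framesInvisible = 0L,
    firstFrame = as.integer(frame),
    R = diag(config$measurement_noise_px^2, 2),
    Q = .kfQ(config$process_noise_px)
  ), class = "KalmanTrack")
}

#' Kalman time update
#'
#' Standard constant-velocity prediction: the state is propagated one frame
#' and the covariance inflated by the process noise. The predicted position
#' is stored in `$predicted`.
#'
#' @param track a `KalmanTrack`.
#' @return the track with predicted state; `$predicted` holds `(x, y)`.
#' @export
kalmanPredict <- function(track) {
  if (!inherits(track, "KalmanTrack")) {
    stop("track is not an initialized KalmanTrack", call. = FALSE)
  }
  track$m <- as.vector(.kfF %*% track$m)
  track$P <- .kfF %*% track$P %*% t(.kfF) + track$Q
  track$predicted <- track$m[1:2]
  track
}

#' Kalman measurement update
#'
#' @param track a predicted `KalmanTrack`.
#' @param z measurement `(x, y)` in pixels.
#' @return the track with filtered state.
#' @export
kalmanUpdate <- function(track, z) {
  S <- .kfH %*% track$P %*% t(.kfH) + track$R
  K <- track$P %*% t(.kfH) %*% solve(S)
  track$m <- as.vector(track$m + K %*% (z - .kfH %*% track$m))
  track$P <- (diag(4) - K %*% .kfH) %*% track$P
  track
}

.pairDist <- function(a, b) {
  # a: n x 2, b: m x 2 -> n x m Euclidean distances
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(matrix(numeric(0), nrow(a), nrow(b)))
  }
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

#' Build the padded assignment cost matrix
#'
#' The real `T x D` block combines, per the configured rule, the distance of
#' each detection to the Kalman-predicted track position (`d_pred`) and to
#' the track's previous coordinates (`d_prev`); the default rule
#' `min(d_pred, d_prev)` lets the previous position act as a fallback when
#' idiosyncratic fly movement defeats the constant-velocity prediction. The
#' matrix is padded to a `(T+D)` square: phantom columns (track
#' non-assignment) and phantom rows (detection non-assignment) cost `con`
#' each, and the bottom-right block carries the transposed real costs so that
#' a pairing is rejected exactly when its cost exceeds both non-assignment
#' alternatives.
#'
#' @param predicted `T x 2` matrix of Kalman-predicted positions.
#' @param previous `T x 2` matrix of last known positions.
#' @param detections `D x 2` matrix of detection centroids.
#' @param con cost of non-assignment (pixels), `>= 0`.
#' @param rule `"min"` (default), `"mean"` or `"pred"` (d_pred only).
#' @return a `CostMatrix` list: `cost` (padded square), `real`, `nTracks`,
#'   `nDetections`, `con`.
#' @export
buildCostMatrix <- function(predicted, previous, detections, con = 11,
                            rule = c("min", "mean", "pred")) {
  rule <- match.arg(rule)
  if (con < 0) stop("con must be non-negative", call. = FALSE)
  predicted <- matrix(predicted, ncol = 2)
  previous <- matrix(previous, ncol = 2)
  detections <- matrix(detections, ncol = 2)
  nT <- nrow(predicted); nD <- nrow(detections)
  dPred <- .pairDist(predicted, detections)
  dPrev <- .pairDist(previous, detections)
  C <- switch(rule,
              min = pmin(dPred, dPrev),
              mean = (dPred + dPrev) / 2,
              pred = dPred)
  side <- nT + nD
  padded <- matrix(con, side, side)
  if (nT > 0L && nD > 0L) {
    padded[seq_len(nT), seq_len(nD)] <- C
    padded[nT + seq_len(nD), nD + seq_len(nT)] <- t(C)
  }
  structure(list(cost = padded, real = C, nTracks = nT, nDetections = nD,
                 con = con), class = "CostMatrix")
}

#' Solve the detection-to-track assignment
#'
#' Minimum-total-cost perfect matching of the padded cost matrix (Hungarian
#' method, via `clue::solve_LSAP`). Tracks matched into phantom columns are
#' unassigned (lost this frame); detections matched from phantom rows are
#' unassigned (candidate new flies).
#'
#' @param cost a `CostMatrix` from [buildCostMatrix()].
#' @return an `Assignment` list: `pairs` data.frame (`track`, `detection`,
#'   1-based indices), `unassignedTracks`, `unassignedDetections`,
#'   `totalCost` of the padded matching.
#' @export
solveAssignment <- function(cost) {
  stopifnot(inherits(cost, "CostMatrix"))
  nT <- cost$nTracks; nD <- cost$nDetections
  if (!all(is.finite(cost$cost))) {
    stop("cost matrix contains non-finite entries", call. = FALSE)
  }
  if (nT + nD == 0L) {
    return(structure(list(pairs = data.frame(track = integer(0),
                                             detection = integer(0)),
                          unassignedTracks = integer(0),
                          unassignedDetections = integer(0), totalCost = 0),
                     class = "Assignment"))
  }
  perm <- as.integer(clue::solve_LSAP(cost$cost))
  tIdx <- seq_len(nT)
  matched <- perm[tIdx] <= nD
  pairs <- data.frame(track = tIdx[matched], detection = perm[tIdx][matched])
  structure(list(
    pairs = pairs,
    unassignedTracks = tIdx[!matched],
    unassignedDetections = setdiff(seq_len(nD), pairs$detection),
    totalCost = sum(cost$cost[cbind(seq_len(nT + nD), perm)])
  ), class = "Assignment")
}

#' Apply one frame's assignment to the track set
#'
#' Assigned tracks take a Kalman measurement update at the detection and
#' record it as this frame's coordinate. Unassigned tracks coast: the last
#' known coordinates are recorded (and fed to the filter as a pseudo-
#' measurement, which decays the velocity of a lost or stationary fly toward
#' zero) and the invisibility counter is incremented. Unassigned detections
#' found new tracks only while the live-track count is below `nFlies`. At
#' capacity, a surplus detection may instead revive a track that has been
#' invisible for at least `max_invisible_frames` (lost-and-found after a
#' fall or long occlusion: the track's Kalman state is re-initialized at the
#' detection); remaining surplus detections are discarded in decreasing
#' order of distance to the nearest unassigned track's previous coordinates
#' (ties broken by ascending detection index).
#'
#' @param tracks list of predicted `KalmanTrack`s.
#' @param detections `D x 2` matrix (or data.frame with `x_px`, `y_px`).
#' @param assignment an `Assignment` consistent with `tracks`/`detections`.
#' @param nFlies known number of flies in the vial.
#' @param config a `GeotaxisConfig`.
#' @param frame 0-based frame index (stamped on new tracks).
#' @return list of updated tracks; each carries `$pos` (recorded coordinate)
#'   and `$seen` (whether it came from a detection) for this frame.
#' @export
updateTracks <- function(tracks, detections, assignment, nFlies,
                         config = geotaxisConfig(), frame = 0L) {
  if (is.data.frame(detections)) {
    detections <- cbind(detections$x_px, detections$y_px)
  }
  detections <- matrix(detections, ncol = 2)
  nT <- length(tracks); nD <- nrow(detections)
  idx <- c(assignment$pairs$track, assignment$unassignedTracks)
  if (nT && (length(idx) != nT || !setequal(idx, seq_len(nT)))) {
    stop("assignment indices inconsistent with tracks", call. = FALSE)
  }
  if (nrow(assignment$pairs) &&
      any(assignment$pairs$detection > nD | assignment$pairs$detection < 1)) {
    stop("assignment indices inconsistent with detections", call. = FALSE)
  }
  for (i in seq_len(nrow(assignment$pairs))) {
    t <- assignment$pairs$track[i]
    z <- detections[assignment$pairs$detection[i], ]
    tr <- kalmanUpdate(tracks[[t]], z)
    tr$lastKnown <- z
    tr$framesInvisible <- 0L
    tr$pos <- z
    tr$seen <- TRUE
    tracks[[t]] <- tr
  }
  for (t in assignment$unassignedTracks) {
    tr <- tracks[[t]]
    prev <- tr$lastKnown
    tr <- kalmanUpdate(tr, prev)
    tr$lastKnown <- prev
    tr$framesInvisible <- tr$framesInvisible + 1L
    tr$pos <- prev
    tr$seen <- FALSE
    tracks[[t]] <- tr
  }
  un <- assignment$unassignedDetections
  capacity <- max(0L, nFlies - nT)
  if (length(un) > capacity) {
    # lost-and-found relocation: a detection that cannot start a new track may
    # revive a track that has been invisible for a long time (a fly lost to a
    # slip, fall or long occlusion reappearing far from its last known
    # position). The Kalman state is re-initialized at the detection.
    lost <- which(vapply(tracks, function(tr) {
      isFALSE(tr$seen) && tr$framesInvisible >= config$max_invisible_frames
    }, logical(1)))
    while (length(un) > capacity && length(lost)) {
      t <- lost[which.max(vapply(tracks[lost], `[[`, integer(1),
                                 "framesInvisible"))]
      d <- un[1]  # surplus detections revive tracks in index order
      z <- detections[d, ]
      fresh <- newTrack(tracks[[t]]$id, z[1], z[2], config = config,
                        frame = frame)
      fresh$firstFrame <- tracks[[t]]$firstFrame
      fresh$pos <- z
      fresh$seen <- TRUE
      tracks[[t]] <- fresh
      lost <- setdiff(lost, t)
      un <- un[-1]
    }
  }
  if (length(un) > capacity) {
    lostPrev <- do.call(rbind, lapply(assignment$unassignedTracks,
                                      function(t) tracks[[t]]$lastKnown))
    d <- if (is.null(lostPrev) || nrow(lostPrev) == 0L) {
      rep(Inf, length(un))
    } else {
      apply(.pairDist(detections[un, , drop = FALSE], lostPrev), 1, min)
    }
    # discard the farthest first; ties resolved by ascending detection index
    discard <- un[order(-d, un)][seq_len(length(un) - capacity)]
    un <- setdiff(un, discard)
  }
  for (d in un) {
    tr <- newTrack(length(tracks) + 1L, detections[d, 1], detections[d, 2],
                   config = config, frame = frame)
    tr$pos <- detections[d, ]
    tr$seen <- TRUE
    tracks[[length(tracks) + 1L]] <- tr
  }
  tracks
}

#' Track per-frame detections into a coordinate matrix
#'
#' Runs the per-frame predict / cost / assign / update loop over
#' pre-computed detections and finalizes the coordinate matrix: frames before
#' a track's first detection are backfilled with that first position
#' (invisible), and if fewer than `n_flies` tracks ever existed, each missing
#' fly receives a constant track at a random coordinate at the bottom of the
#' vial (uniform x across the ROI, y within the bottom 5% of the ROI height,
#' reproducibly seeded from `rng_seed`).
#'
#' @param detections list (one per frame) of data.frames with `x_px`, `y_px`.
#' @param config a `GeotaxisConfig` (`n_flies`, `con`, `cost_rule`, Kalman
#'   and seeding settings).
#' @param roiDim `c(height, width)` of the cropped ROI in pixels.
#' @param vialId integer vial identifier.
#' @param metadata provenance list stored on the result.
#' @return a [CoordinateMatrix] with exactly `n_flies` rows.
#' @export
trackDetections <- function(detections, config, roiDim, vialId = 1L,
                            metadata = list()) {
  nFly <- config$n_flies
  if (nFly < 1L) stop("n_flies must be at least 1", call. = FALSE)
  nFr <- length(detections)
  if (nFr < 1L) stop("no frames to track", call. = FALSE)
  histX <- matrix(NA_real_, nFly, nFr)
  histY <- matrix(NA_real_, nFly, nFr)
  seen <- matrix(FALSE, nFly, nFr)
  tracks <- list()
  for (f in seq_len(nFr)) {
    det <- detections[[f]]
    detXY <- cbind(det$x_px, det$y_px)
    tracks <- lapply(tracks, kalmanPredict)
    pred <- do.call(rbind, lapply(tracks, `[[`, "predicted"))
    prev <- do.call(rbind, lapply(tracks, `[[`, "lastKnown"))
    if (is.null(pred)) pred <- prev <- matrix(numeric(0), 0, 2)
    cost <- buildCostMatrix(pred, prev, detXY, con = config$con,
                            rule = config$cost_rule)
    assignment <- solveAssignment(cost)
    tracks <- updateTracks(tracks, detXY, assignment, nFly, config,
                           frame = f - 1L)
    for (tr in tracks) {
      histX[tr$id, f] <- tr$pos[1]
      histY[tr$id, f] <- tr$pos[2]
      seen[tr$id, f] <- tr$seen
    }
  }
  # backfill frames before each track's first detection with its first position
  for (tr in tracks) {
    if (tr$firstFrame > 0L) {
      pre <- seq_len(tr$firstFrame)
      histX[tr$id, pre] <- histX[tr$id, tr$firstFrame + 1L]
      histY[tr$id, pre] <- histY[tr$id, tr$firstFrame + 1L]
    }
  }
  nLive <- length(tracks)
  if (nLive < nFly) {
    H <- roiDim[1]; W <- roiDim[2]
    .withSeed(config$rng_seed + vialId, {
      for (row in (nLive + 1L):nFly) {
        histX[row, ] <- runif(1, 0, W - 1)
        histY[row, ] <- runif(1, 0.95 * (H - 1), H - 1)
      }
    })
  }
  coordinateMatrix(histX, histY, visible = seen, vialId = vialId,
                   metadata = metadata)
}

#' Track a vial video end to end
#'
#' Detection (median background, segmentation, calibration-based
#' classification, multi-fly splitting) followed by Kalman/Hungarian tracking
#' and finalization.
#'
#' @param stack a vial-cropped [FrameStack].
#' @param thresholds a [DetectionThresholds].
#' @param config a `GeotaxisConfig`.
#' @param vialId integer vial identifier.
#' @return a [CoordinateMatrix] with exactly `config$n_flies` rows and one
#'   coordinate per frame per fly.
#' @export
trackVideo <- function(stack, thresholds, config = geotaxisConfig(),
                       vialId = 1L) {
  det <- detectVideo(stack, thresholds, config)
  trackDetections(det$detections, config, roiDim = dim(stack@frames)[1:2],
                  vialId = vialId,
                  metadata = list(frameRate = stack@frameRate))
}
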