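# Synthetic ground truth: upward-biased correlated random walks with pauses,
# slips, falls and collisions; ellipse rendering on a backlit field; accuracy
# evaluation of tracking output against truth.

#' Simulation parameters
#'
#' Parameters of the synthetic vial: geometry matches the physical assay
#' (140 mm vial at 4.85 px/mm, 30 Hz, up to 7 flies started near the bottom
#' after a startle), and the walk emulates negative geotaxis: an
#' upward-biased correlated random walk with pauses, occasional slips
#' (4.5-12 mm single-frame drops) and falls (> 12 mm), reflective side
#' walls, plus optional non-fly noise streaks. Fly blobs are dark ellipses
#' whose semi-axes are drawn per fly from `flyAxisARange`/`flyAxisBRange`.
#'
#' @param nFlies flies in the vial.
#' @param nFrames frames to simulate.
#' @param frameRateHz acquisition rate (Hz).
#' @param roiWidthPx,roiHeightPx ROI dimensions in pixels.
#' @param pxPerMm pixel scale.
#' @param meanSpeedMmS,sdSpeedMmS per-frame speed draw (mm/s), truncated at 0.
#' @param headingSdRad per-frame heading diffusion (radians).
#' @param upwardBias relaxation rate of the heading toward straight up, in
#'   `[0, 1]`.
#' @param pauseProb per-frame probability of entering a pause while climbing.
#' @param meanPauseFrames mean pause duration (geometric).
#' @param slipRate,fallRate per-frame slip/fall probabilities while climbing.
#' @param startHeightMm flies start uniformly within this height of the
#'   bottom (post-startle bunching).
#' @param collisionRadiusPx centre distance below which two flies count as
#'   overlapping (and render as one merged blob).
#' @param avoidRadiusMm neighbor distance below which a fly steers away
#'   (flies seldom walk through one another); 0 disables avoidance.
#' @param avoidStrength heading correction gain for avoidance, in `[0, 1]`.
#' @param flyAxisARange,flyAxisBRange semi-major/minor axis ranges (px).
#' @param flyDarkness intensity drop of a fly below the backlit field.
#' @param nNoiseObjects number of moving non-fly noise objects.
#' @param noiseKind `"streak"` (long thin smears, rejected by the shape
#'   filter) or `"aberration"` (fly-sized dark spots that jitter much faster
#'   than a walking fly, emulating mobile illumination aberrations that pass
#'   the size/shape filter and tempt the tracker at permissive CON).
#' @param noiseSd additive Gaussian pixel noise s.d. (kept below the 0.06
#'   segmentation threshold).
#' @param collisionFree confine each fly to its own vertical lane so blobs
#'   never merge (used for noiseless-limit and recovery tests).
#' @param rngSeed integer seed; everything downstream is reproducible.
#' @return a validated `SimParams` list.
#' @export
simParams <- function(nFlies = 7, nFrames = 300, frameRateHz = 30,
                      roiWidthPx = 120, roiHeightPx = 680, pxPerMm = 4.85,
                      meanSpeedMmS = 18, sdSpeedMmS = 8,
                      headingSdRad = 0.45, upwardBias = 0.25,
                      pauseProb = 0.02, meanPauseFrames = 20,
                      slipRate = 0.004, fallRate = 0.0015,
                      startHeightMm = 18, collisionRadiusPx = 12,
                      avoidRadiusMm = 4, avoidStrength = 0.8,
                      flyAxisARange = c(5.2, 6.3),
                      flyAxisBRange = c(2.7, 3.3),
                      flyDarkness = 0.55, nNoiseObjects = 0,
                      noiseKind = c("streak", "aberration"),
                      noiseSd = 0.01, collisionFree = FALSE, rngSeed = 0) {
  noiseKind <- match.arg(noiseKind)
  p <- list(nFlies = as.integer(nFlies), nFrames = as.integer(nFrames),
            frameRateHz = frameRateHz, roiWidthPx = as.integer(roiWidthPx),
            roiHeightPx = as.integer(roiHeightPx), pxPerMm = pxPerMm,
            meanSpeedMmS = meanSpeedMmS, sdSpeedMmS = sdSpeedMmS,
            headingSdRad = headingSdRad, upwardBias = upwardBias,
            pauseProb = pauseProb, meanPauseFrames = meanPauseFrames,
            slipRate = slipRate, fallRate = fallRate,
            startHeightMm = startHeightMm,
            collisionRadiusPx = collisionRadiusPx,
            avoidRadiusMm = avoidRadiusMm, avoidStrength = avoidStrength,
            flyAxisARange = flyAxisARange, flyAxisBRange = flyAxisBRange,
            flyDarkness = flyDarkness, nNoiseObjects = as.integer(nNoiseObjects),
            noiseKind = noiseKind,
            noiseSd = noiseSd, collisionFree = isTRUE(collisionFree),
            rngSeed = as.integer(rngSeed))
  rates <- c(p$pauseProb, p$slipRate, p$fallRate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (p$nFlies < 0 || p$nFrames < 2) stop("need nFlies >= 0, nFrames >= 2",
                                          call. = FALSE)
  if (p$upwardBias < 0 || p$upwardBias > 1) {
    stop("upwardBias must lie in [0, 1]", call. = FALSE)
  }
  class(p) <- "SimParams"
  p
}

#' Construct a GroundTruth from coordinate arrays
#'
#' Wraps externally crafted trajectories (e.g. exact constant-velocity paths
#' for closed-form tests) in the [GroundTruth] container.
#'
#' @param x,y numeric `nFlies x nFrames` matrices, 0-based pixels.
#' @param params a `SimParams` describing the arena.
#' @param state optional state matrix (defaults to all `"climb"`).
#' @param drops optional planted-drop data.frame.
#' @return a [GroundTruth].
#' @export
groundTruth <- function(x, y, params, state = NULL, drops = NULL) {
  if (is.null(state)) state <- matrix("climb", nrow(x), ncol(x))
  if (is.null(drops)) {
    drops <- data.frame(fly = integer(0), frame = integer(0),
                        kind = character(0), dropMm = numeric(0),
                        preDropHeightMm = numeric(0))
  }
  new("GroundTruth", x = x, y = y, state = state, drops = drops,
      params = unclass(params))
}

#' Simulate ground-truth fly trajectories
#'
#' Per-fly state machine over `{climb, pause, slip, fall}`. Climbing is an
#' upward-biased correlated random walk: the heading relaxes toward straight
#' up at rate `upwardBias` with Gaussian diffusion, and the per-frame speed
#' is drawn afresh. Slips displace the fly down by a uniform draw from
#' `[4.5, 12]` mm and falls by a uniform draw from `(12, y]` mm (never below
#' the floor); both require sufficient height and occupy a single frame.
#' Walls reflect, with a body-clearance margin so blobs are never clipped at
#' the ROI border; a fly reaching the ceiling turns around and descends for
#' a while instead of accumulating at the top. Flies are simulated jointly:
#' a fly steers away from a neighbor closer than `avoidRadiusMm`. Fully
#' seeded and reproducible.
#'
#' @param params a `SimParams`.
#' @return a [GroundTruth] with positions, states and planted drop events.
#' @export
simulateTrajectories <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  p <- params
  clr <- 1.5  # body clearance (mm): a fly's centroid sits off the walls
  Wmm <- (p$roiWidthPx - 1) / p$pxPerMm - clr
  Hmm <- (p$roiHeightPx - 1) / p$pxPerMm - clr
  dt <- 1 / p$frameRateHz
  slipMin <- 4.5; slipMax <- 12
  xs <- matrix(0, p$nFlies, p$nFrames)
  ys <- matrix(0, p$nFlies, p$nFrames)
  st <- matrix("climb", p$nFlies, p$nFrames)
  drops <- list()
  wrap <- function(a) atan2(sin(a), cos(a))
  nF <- p$nFlies
  .withSeed(p$rngSeed, {
    if (p$collisionFree && nF > 0) {
      # lane buffers wider than a blob keep even adjacent-lane flies from
      # merging in the rendered image
      laneW <- (Wmm - clr) / nF
      laneLo <- clr + (seq_len(nF) - 1) * laneW + 1.75
      laneHi <- clr + seq_len(nF) * laneW - 1.75
      if (any(laneHi - laneLo < 0.5)) {
        stop("ROI too narrow for collision-free lanes with this fly count",
             call. = FALSE)
      }
    } else {
      laneLo <- rep(clr, nF); laneHi <- rep(Wmm, nF)
    }
    x <- runif(nF, laneLo, laneHi)
    y <- runif(nF, clr, min(p$startHeightMm, Hmm))
    phi <- pi / 2 + rnorm(nF, 0, p$headingSdRad)
    mode <- rep("climb", nF)
    pauseLeft <- integer(nF)
    biasDir <- rep(pi / 2, nF)  # heading attractor: up, or down in a descend bout
    descendLeft <- integer(nF)
    if (nF > 0) { xs[, 1] <- x; ys[, 1] <- y }
    for (t in seq_len(p$nFrames)[-1]) {
      xPrev <- x; yPrev <- y
      for (f in seq_len(nF)) {
        if (mode[f] == "pause") {
          st[f, t] <- "pause"
          pauseLeft[f] <- pauseLeft[f] - 1L
          if (pauseLeft[f] <= 0L) mode[f] <- "climb"
        } else {
          u <- runif(1)
          if (u < p$fallRate && y[f] - clr > slipMax) {
            d <- runif(1, slipMax, y[f] - clr)
            y[f] <- y[f] - d
            st[f, t] <- "fall"
            drops[[length(drops) + 1L]] <-
              data.frame(fly = f, frame = t - 1L, kind = "fall",
                         dropMm = d, preDropHeightMm = y[f] + d)
          } else if (u < p$fallRate + p$slipRate && y[f] - clr > slipMin) {
            d <- runif(1, slipMin, min(slipMax, y[f] - clr))
            y[f] <- y[f] - d
            st[f, t] <- "slip"
            drops[[length(drops) + 1L]] <-
              data.frame(fly = f, frame = t - 1L, kind = "slip",
                         dropMm = d, preDropHeightMm = y[f] + d)
          } else if (u < p$fallRate + p$slipRate + p$pauseProb) {
            mode[f] <- "pause"
            st[f, t] <- "pause"
            pauseLeft[f] <- max(1L, rgeom(1, 1 / p$meanPauseFrames) + 1L)
          } else {
            # correlated random walk step with upward bias
            if (descendLeft[f] > 0L) {
              descendLeft[f] <- descendLeft[f] - 1L
              if (descendLeft[f] == 0L) biasDir[f] <- pi / 2
            }
            turn <- p$upwardBias * wrap(biasDir[f] - phi[f]) +
              rnorm(1, 0, p$headingSdRad)
            if (!p$collisionFree && nF > 1 && p$avoidStrength > 0) {
              # steer away from the nearest neighbor within the avoidance
              # radius (flies rarely walk through one another)
              dn <- sqrt((xPrev - xPrev[f])^2 + (yPrev - yPrev[f])^2)
              dn[f] <- Inf
              j <- which.min(dn)
              if (dn[j] < p$avoidRadiusMm) {
                away <- atan2(yPrev[f] - yPrev[j], xPrev[f] - xPrev[j])
                turn <- turn + p$avoidStrength *
                  (1 - dn[j] / p$avoidRadiusMm) * wrap(away - phi[f])
              }
            }
            phi[f] <- wrap(phi[f] + turn)
            sp <- max(0, rnorm(1, p$meanSpeedMmS, p$sdSpeedMmS))
            x[f] <- x[f] + sp * dt * cos(phi[f])
            y[f] <- y[f] + sp * dt * sin(phi[f])
            # reflect off walls; a fly reaching the top turns around rather
            # than piling at the ceiling (transient positive geotaxis)
            if (x[f] < laneLo[f]) {
              x[f] <- 2 * laneLo[f] - x[f]; phi[f] <- wrap(pi - phi[f])
            }
            if (x[f] > laneHi[f]) {
              x[f] <- 2 * laneHi[f] - x[f]; phi[f] <- wrap(pi - phi[f])
            }
            if (y[f] > Hmm) {
              y[f] <- 2 * Hmm - y[f]
              phi[f] <- wrap(-phi[f])
              biasDir[f] <- -pi / 2
              descendLeft[f] <- 1L + rgeom(1, 1 / 40)
            }
            if (y[f] < clr) {
              y[f] <- 2 * clr - y[f]; phi[f] <- wrap(-phi[f])
              biasDir[f] <- pi / 2
            }
            x[f] <- min(max(x[f], laneLo[f]), laneHi[f])
            y[f] <- min(max(y[f], clr), Hmm)
          }
        }
        xs[f, t] <- x[f]
        ys[f, t] <- y[f]
      }
    }
  })
  drops <- if (length(drops)) do.call(rbind, drops) else
    data.frame(fly = integer(0), frame = integer(0), kind = character(0),
               dropMm = numeric(0), preDropHeightMm = numeric(0))
  # physics mm (y up) -> image px (y down)
  groundTruth(x = xs * p$pxPerMm,
              y = (p$roiHeightPx - 1) - ys * p$pxPerMm,
              params = p, state = st, drops = drops)
}

#' First-crossing times planted in a ground truth
#'
#' Times (seconds) at which each fly first exceeds a target height above the
#' vial bottom, computed from the true trajectories.
#'
#' @param truth a [GroundTruth].
#' @param targetHeightMm target height (mm).
#' @return data.frame `fly`, `time_s` (NA rows omitted).
#' @export
firstCrossings <- function(truth, targetHeightMm) {
  p <- truth@params
  dt <- 1 / p$frameRateHz
  yMm <- ((p$roiHeightPx - 1) - truth@y) / p$pxPerMm
  out <- lapply(seq_len(nrow(yMm)), function(f) {
    i <- which(yMm[f, ] > targetHeightMm)[1]
    if (is.na(i)) NULL else data.frame(fly = f, time_s = (i - 1) * dt)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(fly = integer(0), time_s = numeric(0)) else out
}

#' Fraction of frames containing an overlapping fly pair
#'
#' @param truth a [GroundTruth].
#' @param radiusPx overlap radius; defaults to the simulation's
#'   `collisionRadiusPx`.
#' @return fraction of frames in which at least one pair of flies is closer
#'   than `radiusPx`.
#' @export
overlapFraction <- function(truth, radiusPx = truth@params$collisionRadiusPx) {
  n <- ncol(truth@x)
  if (nrow(truth@x) < 2L) return(0)
  hit <- vapply(seq_len(n), function(t) {
    d <- dist(cbind(truth@x[, t], truth@y[, t]))
    any(d < radiusPx)
  }, logical(1))
  mean(hit)
}

# Paint one soft-edged dark ellipse onto a frame (in place), centre (cx, cy)
# 0-based px, semi-axes (a, b), orientation alpha. Coverage ramps linearly
# over ~1 px at the boundary so areas stay stable across subpixel positions.
.paintEllipse <- function(frame, cx, cy, a, b, alpha, depth) {
  H <- nrow(frame); W <- ncol(frame)
  r <- ceiling(max(a, b)) + 2L
  c0 <- max(0L, floor(cx) - r); c1 <- min(W - 1L, ceiling(cx) + r)
  r0 <- max(0L, floor(cy) - r); r1 <- min(H - 1L, ceiling(cy) + r)
  if (c0 > c1 || r0 > r1) return(frame)
  px <- seq(c0, c1); py <- seq(r0, r1)
  dx <- outer(py * 0, px - cx, "+")
  dy <- outer(py - cy, px * 0, "+")
  ca <- cos(alpha); sa <- sin(alpha)
  u <- (dx * ca + dy * sa) / a
  v <- (-dx * sa + dy * ca) / b
  q <- sqrt(u * u + v * v)
  edge <- 1 / min(a, b)  # ~1 px soft edge in normalized units
  cov <- pmin(1, pmax(0, (1 - q) / edge + 0.5))
  sub <- frame[r0:r1 + 1L, c0:c1 + 1L]
  frame[r0:r1 + 1L, c0:c1 + 1L] <- pmin(sub, pmax(0, sub - depth * cov))
  frame
}

#' Render a ground truth as a synthetic vial video
#'
#' Bright backlit field (base intensity ~0.9 with a smooth vertical
#' illumination gradient and sub-threshold Gaussian pixel noise) on which
#' each fly is a dark anti-aliased ellipse oriented along its velocity.
#' Overlapping flies merge into one blob, reproducing occlusion; optional
#' noise streaks emulate illumination aberrations. Rendering is seeded from
#' the simulation seed, so identical parameters give bit-identical videos.
#'
#' @param truth a [GroundTruth].
#' @param params a `SimParams`; defaults to the truth's own.
#' @return a [FrameStack].
#' @export
renderVideo <- function(truth, params = NULL) {
  p <- if (is.null(params)) truth@params else unclass(params)
  H <- p$roiHeightPx; W <- p$roiWidthPx
  nFr <- ncol(truth@x); nFly <- nrow(truth@x)
  bg <- matrix(0.88, H, W) + 0.04 * (seq_len(H) - 1) / max(1, H - 1)
  frames <- array(0, dim = c(H, W, nFr))
  .withSeed(p$rngSeed + 1000003L, {
    axA <- runif(max(nFly, 1), p$flyAxisARange[1], p$flyAxisARange[2])
    axB <- runif(max(nFly, 1), p$flyAxisBRange[1], p$flyAxisBRange[2])
    if (p$nNoiseObjects > 0) {
      aberrant <- identical(p$noiseKind, "aberration")
      nsX <- runif(p$nNoiseObjects, 8, W - 9)
      nsY <- runif(p$nNoiseObjects, 8, H - 9)
      nsVx <- runif(p$nNoiseObjects, -2.5, 2.5)
      nsVy <- runif(p$nNoiseObjects, -2.5, 2.5)
      if (aberrant) {
        # fly-sized spots that jitter far faster than a walking fly
        nsA <- runif(p$nNoiseObjects, p$flyAxisARange[1], p$flyAxisARange[2])
        nsB <- runif(p$nNoiseObjects, p$flyAxisBRange[1], p$flyAxisBRange[2])
        nsJit <- matrix(rnorm(2 * p$nNoiseObjects * nFr, 0, 13),
                        ncol = 2 * p$nNoiseObjects)
      } else {
        nsA <- runif(p$nNoiseObjects, 9, 13)   # long thin streaks
        nsB <- runif(p$nNoiseObjects, 0.6, 0.9)
      }
      nsAng <- runif(p$nNoiseObjects, 0, pi)
    }
    noise <- array(rnorm(length(frames), 0, p$noiseSd), dim = dim(frames))
    for (t in seq_len(nFr)) {
      fr <- bg
      for (f in seq_len(nFly)) {
        tPrev <- max(1L, t - 1L)
        vx <- truth@x[f, t] - truth@x[f, tPrev]
        vy <- truth@y[f, t] - truth@y[f, tPrev]
        if (t == 1L && nFr > 1L) {
          vx <- truth@x[f, 2] - truth@x[f, 1]
          vy <- truth@y[f, 2] - truth@y[f, 1]
        }
        alpha <- if (abs(vx) + abs(vy) < 1e-9) 0 else atan2(vy, vx)
        fr <- .paintEllipse(fr, truth@x[f, t], truth@y[f, t],
                            axA[f], axB[f], alpha, p$flyDarkness)
      }
      if (p$nNoiseObjects > 0) {
        for (k in seq_len(p$nNoiseObjects)) {
          if (aberrant) {
            cx <- (nsX[k] + cumsum(nsJit[seq_len(t), 2 * k - 1])[t]) %% W
            cy <- (nsY[k] + cumsum(nsJit[seq_len(t), 2 * k])[t]) %% H
            fr <- .paintEllipse(fr, cx, cy, nsA[k], nsB[k], nsAng[k],
                                p$flyDarkness)
          } else {
            cx <- (nsX[k] + t * nsVx[k]) %% W
            cy <- (nsY[k] + t * nsVy[k]) %% H
            fr <- .paintEllipse(fr, cx, cy, nsA[k], nsB[k], nsAng[k], 0.3)
          }
        }
      }
      frames[, , t] <- pmin(1, pmax(0, fr + noise[, , t]))
    }
  })
  frameStack(frames, frameRate = p$frameRateHz)
}

#' Score tracking output against ground truth
#'
#' Frame-by-frame, tracked positions are matched to true positions by
#' minimum-total-distance assignment (identity-agnostic, matching the
#' anonymized use of the coordinates downstream). A position is correct when
#' its matched distance is below `tolPx`. Identity switches are frame
#' transitions at which the matching permutation changes; the
#' missing-coordinate fraction is the fraction of coordinates not backed by
#' a detection (coasting or bottom seeding); the large-jump statistic
#' averages each track's top 1% of frame-to-frame displacements, normalized
#' to the ROI (vial) height.
#'
#' @param truth a [GroundTruth].
#' @param coords a [CoordinateMatrix] of the same fly and frame count.
#' @param tolPx correctness tolerance in pixels (default 10).
#' @return an [AccuracyReport].
#' @export
evaluateTracking <- function(truth, coords, tolPx = 10) {
  if (!identical(dim(truth@x), dim(coords@x))) {
    stop("truth and coords have different shapes", call. = FALSE)
  }
  nFly <- nrow(truth@x); nFr <- ncol(truth@x)
  errs <- matrix(NA_real_, nFly, nFr)
  perms <- matrix(NA_integer_, nFly, nFr)
  for (t in seq_len(nFr)) {
    D <- .pairDist(cbind(coords@x[, t], coords@y[, t]),
                   cbind(truth@x[, t], truth@y[, t]))
    perm <- if (nFly == 1L) 1L else as.integer(clue::solve_LSAP(D))
    perms[, t] <- perm
    errs[, t] <- D[cbind(seq_len(nFly), perm)]
  }
  correct <- errs < tolPx
  switches <- if (nFr > 1L) {
    sum(vapply(2:nFr, function(t) any(perms[, t] != perms[, t - 1]),
               logical(1))) / (nFr - 1)
  } else 0
  jump <- mean(vapply(seq_len(nFly), function(f) {
    d <- sqrt(diff(coords@x[f, ])^2 + diff(coords@y[f, ])^2)
    k <- max(1L, ceiling(0.01 * length(d)))
    mean(sort(d, decreasing = TRUE)[seq_len(k)])
  }, numeric(1))) / truth@params$roiHeightPx
  new("AccuracyReport",
      fractionCorrect = mean(correct),
      meanErrorPx = if (any(correct)) mean(errs[correct]) else NA_real_,
      errorsPx = as.vector(errs),
      switchFraction = switches,
      missingFraction = mean(!coords@visible),
      largeJumpFraction = jump,
      tolPx = tolPx, nFlies = as.integer(nFly), nFrames = as.integer(nFr))
}

#' Build a calibration table from rendered synthetic objects
#'
#' Renders isolated single flies, merged fly pairs and noise streaks with the
#' same ellipse renderer used for videos, measures each through the
#' segmentation/measurement pipeline, and labels the rows by construction.
#' Single-fly sizes are drawn from `singleAxisARange`/`singleAxisBRange`,
#' deliberately wider than the default video fly sizes, so the video flies
#' sit inside the calibrated strain's size spread (as experimental flies sit
#' inside a strain calibration).
#'
#' @param params a `SimParams` (pixel scale, darkness, threshold geometry).
#' @param nSingle,nMulti,nNoise example counts per class.
#' @param singleAxisARange,singleAxisBRange semi-axis ranges for calibration
#'   singles (px).
#' @param seed RNG seed.
#' @param diffThreshold segmentation threshold.
#' @return a [CalibrationTable].
#' @export
calibrateFromSimulation <- function(params = simParams(), nSingle = 150,
                                    nMulti = 80, nNoise = 40,
                                    singleAxisARange = c(4.0, 7.2),
                                    singleAxisBRange = c(2.0, 3.8),
                                    seed = 12345, diffThreshold = 0.06) {
  p <- unclass(params)
  canvas <- 48L
  bgv <- 0.9
  measureOne <- function(paint) {
    fr <- paint(matrix(bgv, canvas, canvas))
    mask <- segmentFrame(fr, matrix(bgv, canvas, canvas), diffThreshold)
    obj <- extractObjects(mask, 8)
    if (nrow(obj) == 0L) return(NULL)
    obj[which.max(obj$area_px), c("area_px", "major_axis_px", "minor_axis_px")]
  }
  rows <- .withSeed(seed, {
    out <- list()
    for (i in seq_len(nSingle)) {
      a <- runif(1, singleAxisARange[1], singleAxisARange[2])
      b <- runif(1, singleAxisBRange[1], singleAxisBRange[2])
      ang <- runif(1, 0, pi)
      cx <- canvas / 2 + runif(1, -0.5, 0.5)
      cy <- canvas / 2 + runif(1, -0.5, 0.5)
      m <- measureOne(function(fr) .paintEllipse(fr, cx, cy, a, b, ang,
                                                 p$flyDarkness))
      if (!is.null(m)) out[[length(out) + 1L]] <- cbind(m, label = "single")
    }
    for (i in seq_len(nMulti)) {
      a1 <- runif(1, singleAxisARange[1], singleAxisARange[2])
      b1 <- runif(1, singleAxisBRange[1], singleAxisBRange[2])
      a2 <- runif(1, singleAxisARange[1], singleAxisARange[2])
      b2 <- runif(1, singleAxisBRange[1], singleAxisBRange[2])
      ang1 <- runif(1, 0, pi); ang2 <- runif(1, 0, pi)
      off <- runif(1, 0.35, 0.95) * (a1 + a2)
      dir <- runif(1, 0, 2 * pi)
      m <- measureOne(function(fr) {
        fr <- .paintEllipse(fr, canvas / 2, canvas / 2, a1, b1, ang1,
                            p$flyDarkness)
        .paintEllipse(fr, canvas / 2 + off * cos(dir),
                      canvas / 2 + off * sin(dir), a2, b2, ang2, p$flyDarkness)
      })
      if (!is.null(m)) out[[length(out) + 1L]] <- cbind(m, label = "multi")
    }
    for (i in seq_len(nNoise)) {
      long <- runif(1, 8, 14); thin <- runif(1, 0.55, 0.9)
      ang <- runif(1, 0, pi)
      m <- measureOne(function(fr) .paintEllipse(fr, canvas / 2, canvas / 2,
                                                 long, thin, ang, 0.3))
      if (!is.null(m)) out[[length(out) + 1L]] <- cbind(m, label = "noise")
    }
    out
  })
  calibrationTable(do.call(rbind, rows))
}

#' Write ground truth to CSV
#'
#' Long format `frame,fly_id,x_px,y_px,state` (frames 0-based).
#' @param truth a [GroundTruth].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  nFly <- nrow(truth@x); nFr <- ncol(truth@x)
  df <- data.frame(frame = rep(seq_len(nFr) - 1L, each = nFly),
                   fly_id = rep(seq_len(nFly), nFr),
                   x_px = as.vector(truth@x), y_px = as.vector(truth@y),
                   state = as.vector(truth@state))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ground truth from CSV
#' @param path CSV written by [writeGroundTruth()].
#' @param params the `SimParams` of the simulation.
#' @return a [GroundTruth].
#' @export
readGroundTruth <- function(path, params) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  nFly <- max(df$fly_id); nFr <- max(df$frame) + 1L
  df <- df[order(df$frame, df$fly_id), ]
  groundTruth(x = matrix(df$x_px, nFly, nFr),
              y = matrix(df$y_px, nFly, nFr), params = params,
              state = matrix(df$state, nFly, nFr))
}

#' Standard synthetic benchmark conditions
#'
#' The frozen study conditions used to benchmark the tracker: 7 flies, 300
#' frames at 30 Hz in a 120 x 680 px vial ROI, with start bunching and walk
#' parameters under which about 3.5% of frames contain an overlapping fly
#' pair (the collision frequency observed in real recordings).
#'
#' @param seed RNG seed for the video.
#' @return a `SimParams`.
#' @export
benchmarkParams <- function(seed = 0) {
  simParams(rngSeed = seed)
}

#' Run the synthetic tracking benchmark
#'
#' For each seed: simulate, render, calibrate-derive thresholds (shared
#' across videos), track with the configured CON, and score against truth.
#'
#' @param seeds integer vector of video seeds.
#' @param config a `GeotaxisConfig`.
#' @param tolPx evaluation tolerance (px).
#' @param paramsFun function mapping a seed to `SimParams`.
#' @return list with `reports` (one [AccuracyReport] per seed), `overlap`
#'   (per-video overlap-frame fractions), and `thresholds`.
#' @export
runBenchmark <- function(seeds = 0:9, config = geotaxisConfig(),
                         tolPx = 10, paramsFun = benchmarkParams) {
  calib <- calibrateFromSimulation(paramsFun(seeds[1]))
  thr <- deriveThresholds(calib, areaPercentile = config$area_percentile,
                          ratioTrim = config$ratio_trim)
  reports <- list(); overlap <- numeric(0)
  for (s in seeds) {
    p <- paramsFun(s)
    truth <- simulateTrajectories(p)
    stack <- renderVideo(truth)
    cm <- trackVideo(stack, thr, config, vialId = 1L)
    reports[[length(reports) + 1L]] <- evaluateTracking(truth, cm, tolPx)
    overlap <- c(overlap, overlapFraction(truth))
  }
  list(reports = reports, overlap = overlap, thresholds = thr)
}

#' Sweep the cost of non-assignment on a fixed benchmark
#'
#' Re-tracks pre-computed detections at each CON value and scores the two
#' error families of the optimization: the missing-coordinate rate
#' (normalized to the maximum over the sweep) and the large-jump statistic,
#' combined with weights 1 and 0.1 into the weighted error whose interior
#' minimum locates the optimal CON.
#'
#' @param detectionsList list of per-video detection lists (from
#'   [detectVideo()]).
#' @param truths list of matching [GroundTruth] objects.
#' @param cons CON values to sweep.
#' @param config a `GeotaxisConfig`.
#' @param tolPx evaluation tolerance.
#' @return data.frame: `con`, `missingRate`, `missingNorm`, `largeJump`,
#'   `weightedError`.
#' @export
conSweep <- function(detectionsList, truths, cons = 1:17,
                     config = geotaxisConfig(), tolPx = 10) {
  res <- lapply(cons, function(con) {
    cfg <- config; cfg$con <- con
    miss <- jump <- numeric(0)
    for (i in seq_along(detectionsList)) {
      p <- truths[[i]]@params
      cm <- trackDetections(detectionsList[[i]], cfg,
                            roiDim = c(p$roiHeightPx, p$roiWidthPx))
      rep <- evaluateTracking(truths[[i]], cm, tolPx)
      miss <- c(miss, rep@missingFraction)
      jump <- c(jump, rep@largeJumpFraction)
    }
    data.frame(con = con, missingRate = mean(miss), largeJump = mean(jump))
  })
  res <- do.call(rbind, res)
  res$missingNorm <- if (max(res$missingRate) > 0) {
    res$missingRate / max(res$missingRate)
  } else 0
  res$weightedError <- 1 * res$missingNorm + 0.1 * res$largeJump
  res
}
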