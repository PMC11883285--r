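# Analytics: unit conversion, speed/angle kinematics, climbing curves,
# turning rate, slip/fall detection, bootstrapped rho+/rho- ratio, nested
# group summaries.

#' Convert a coordinate matrix to physical trajectories
#'
#' Maps image-convention pixel coordinates (origin top-left, y downward) to
#' physics convention: millimetres, y measured upward from the vial bottom.
#' `x_mm = x_px / pxPerMm`, `y_mm = (roiHeightPx - y_px) / pxPerMm`, clamped
#' to `[0, vialHeightMm]`.
#'
#' @param matrix a [CoordinateMatrix].
#' @param roiHeightPx height of the cropped ROI in pixels.
#' @param pxPerMm positive pixel scale.
#' @param vialHeightMm vial height in mm (clamp ceiling).
#' @return list of trajectories, one per fly: data.frames with `x_mm`,
#'   `y_mm` and attributes `dt` (NULL unless the matrix carries a frame
#'   rate) and `flyId`.
#' @export
toPhysical <- function(matrix, roiHeightPx, pxPerMm, vialHeightMm = 140) {
  if (pxPerMm <= 0) stop("pxPerMm must be positive", call. = FALSE)
  dt <- if (!is.null(matrix@metadata$frameRate)) 1 / matrix@metadata$frameRate
  lapply(seq_len(nFlies(matrix)), function(i) {
    traj <- data.frame(
      x_mm = matrix@x[i, ] / pxPerMm,
      y_mm = pmin(pmax((roiHeightPx - matrix@y[i, ]) / pxPerMm, 0), vialHeightMm)
    )
    attr(traj, "dt") <- dt
    attr(traj, "flyId") <- i
    traj
  })
}

#' Frame-pair speed and movement-angle series
#'
#' For each consecutive frame pair computes the Euclidean displacement
#' `dr = sqrt(dx^2 + dy^2)` (mm), the speed `s = dr / dt` (mm/s), and the
#' movement direction `theta = atan2(dy, |dx|)` in degrees. Taking `|dx|`
#' makes leftward and rightward movement indistinguishable, so theta spans
#' `[-90, 90]` with +90 straight up and -90 straight down. Pairs with
#' `dr >= gateMm` (default 4 mm) are abnormally large frame-frame locomotion
#' - position artifacts, slips, falls, flight - and are gated out of the
#' speed-angle data; a stationary pair (`dr = 0`) has undefined theta.
#'
#' @param traj trajectory data.frame with `x_mm`, `y_mm` (length >= 2).
#' @param gateMm displacement gate in mm; pairs at or above it carry no
#'   `(s, theta)`.
#' @param dt seconds per frame; defaults to the trajectory's `dt` attribute.
#' @return data.frame, one row per frame pair: `pair` (0-based index of the
#'   earlier frame), `dr_mm`, `gated`, `speed_mm_s`, `theta_deg` (NA when
#'   gated or undefined).
#' @export
speedAngle <- function(traj, gateMm = 4, dt = attr(traj, "dt")) {
  if (nrow(traj) < 2L) stop("trajectory needs at least 2 frames", call. = FALSE)
  if (is.null(dt)) stop("dt not supplied and not carried by trajectory",
                        call. = FALSE)
  dx <- diff(traj$x_mm)
  dy <- diff(traj$y_mm)
  dr <- sqrt(dx^2 + dy^2)
  gated <- dr >= gateMm
  speed <- ifelse(gated, NA_real_, dr / dt)
  theta <- ifelse(gated | dr == 0, NA_real_,
                  atan2(dy, abs(dx)) * 180 / pi)
  data.frame(pair = seq_along(dr) - 1L, dr_mm = dr, gated = gated,
             speed_mm_s = speed, theta_deg = theta)
}

#' Trajectory turning rate
#'
#' Counts non-zero changes in movement direction between consecutive defined
#' angles and divides by elapsed time. Only adjacent frame pairs where both
#' angles are defined contribute; any gated or stationary pair breaks the
#' chain. The default tolerance is effectively exact-change counting on
#' pixel-quantized data.
#'
#' @param series a speed-angle data.frame from [speedAngle()].
#' @param dt seconds per frame.
#' @param angleTolDeg angular changes larger than this count as turns.
#' @return turns per second.
#' @export
turningRate <- function(series, dt, angleTolDeg = 1e-6) {
  th <- series$theta_deg
  ok <- !is.na(th)
  adjacent <- ok[-1] & ok[-length(ok)] &
    diff(series$pair) == 1L
  dtheta <- abs(diff(th))[adjacent]
  elapsed <- nrow(series) * dt
  sum(dtheta > angleTolDeg) / elapsed
}

#' Climbing curve at a target height
#'
#' Records, per fly and trial, the time of the first frame at which the fly
#' is above the target height; a fly that later shows positive geotaxis and
#' drops below the target stays counted. Single-trial curves are staircases
#' with unit steps; across trials the mean curve steps by `1/N_trials` with a
#' s.e.m. band computed across trials at every step time.
#'
#' @param trials list of trials, each a list of trajectory data.frames
#'   (`x_mm`, `y_mm`) sharing `dt` and fly count.
#' @param targetHeightMm target height above the vial bottom (mm).
#' @param dt seconds per frame.
#' @param vialHeightMm vial height; targets above it are rejected.
#' @return a `ClimbingCurve` list: `crossings` data.frame (`trial`, `fly`,
#'   `time_s`), `curve` data.frame (`time_s`, `mean`, `sem`), `target`,
#'   `nTrials`, `nFlies`.
#' @export
climbingCurve <- function(trials, targetHeightMm, dt, vialHeightMm = 140) {
  if (targetHeightMm > vialHeightMm) {
    stop("target height exceeds vial height", call. = FALSE)
  }
  nTrials <- length(trials)
  nFliesPer <- length(trials[[1]])
  crossings <- do.call(rbind, lapply(seq_len(nTrials), function(tr) {
    do.call(rbind, lapply(seq_len(length(trials[[tr]])), function(f) {
      y <- trials[[tr]][[f]]$y_mm
      i <- which(y > targetHeightMm)[1]
      if (is.na(i)) return(NULL)
      data.frame(trial = tr, fly = f, time_s = (i - 1) * dt)
    }))
  }))
  if (is.null(crossings)) {
    crossings <- data.frame(trial = integer(0), fly = integer(0),
                            time_s = numeric(0))
  }
  times <- sort(unique(crossings$time_s))
  if (length(times)) {
    counts <- vapply(times, function(t) {
      vapply(seq_len(nTrials), function(tr) {
        sum(crossings$trial == tr & crossings$time_s <= t)
      }, numeric(1))
    }, numeric(nTrials))
    counts <- matrix(counts, nrow = nTrials)
    mean_ <- colMeans(counts)
    sem <- apply(counts, 2, sd) / sqrt(nTrials)
  } else {
    mean_ <- numeric(0); sem <- numeric(0)
  }
  structure(list(
    crossings = crossings,
    curve = data.frame(time_s = times, mean = mean_, sem = sem),
    target = targetHeightMm, nTrials = nTrials, nFlies = nFliesPer
  ), class = "ClimbingCurve")
}

#' @export
print.ClimbingCurve <- function(x, ...) {
  cat("ClimbingCurve: target", x$target, "mm,", x$nTrials, "trials,",
      x$nFlies, "flies/trial;", nrow(x$crossings), "crossings, terminal mean",
      if (nrow(x$curve)) format(x$curve$mean[nrow(x$curve)]) else 0, "\n")
  invisible(x)
}

#' Plot a climbing curve
#' @param x a `ClimbingCurve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ClimbingCurve <- function(x, ...) {
  if (!nrow(x$curve)) {
    graphics::plot(0, 0, type = "n", xlab = "time (s)", ylab = "flies above target",
                   ...)
    return(invisible(x))
  }
  graphics::plot(x$curve$time_s, x$curve$mean, type = "s", xlab = "time (s)",
                 ylab = "flies above target",
                 main = paste0("target ", x$target, " mm"), ...)
  graphics::lines(x$curve$time_s, x$curve$mean + x$curve$sem, type = "s",
                  lty = 2, col = "grey50")
  graphics::lines(x$curve$time_s, pmax(0, x$curve$mean - x$curve$sem),
                  type = "s", lty = 2, col = "grey50")
  invisible(x)
}

#' Detect slips and falls in a trajectory
#'
#' A vertical drop between consecutive frames of more than about a body
#' length and up to three body lengths (`slipMinMm <= -dy <= slipMaxMm`,
#' default 4.5-12 mm) is a slip; a larger drop (`-dy > slipMaxMm`) is a fall.
#' Each event records the height just before the drop and the ratio of the
#' drop to its maximum possible size (the pre-drop height above the vial
#' bottom), which is 1 when a drop takes the fly all the way down.
#'
#' @param traj trajectory data.frame with `y_mm`.
#' @param slipMinMm,slipMaxMm slip bounds in mm.
#' @return data.frame: `frame` (0-based index of the frame after the drop),
#'   `kind` (`"slip"`/`"fall"`), `drop_mm`, `pre_drop_height_mm`, `ratio`.
#' @export
detectDrops <- function(traj, slipMinMm = 4.5, slipMaxMm = 12) {
  if (nrow(traj) < 2L) stop("trajectory needs at least 2 frames", call. = FALSE)
  drop <- -diff(traj$y_mm)
  i <- which(drop >= slipMinMm)
  data.frame(
    frame = i,
    kind = ifelse(drop[i] > slipMaxMm, "fall", "slip"),
    drop_mm = drop[i],
    pre_drop_height_mm = traj$y_mm[i],
    ratio = drop[i] / traj$y_mm[i]
  )
}

.spearman <- function(x, y) suppressWarnings(cor(x, y, method = "spearman"))

#' Bootstrapped ratio of speed-angle rank correlations
#'
#' Directional-bias metric: speed-angle pairs are resampled with replacement
#' (`N_sample` equal to the data size), split into upward (`theta > 0`) and
#' downward (`theta < 0`) strata, and the Spearman correlations `rho_+` and
#' `rho_-` and their ratio `rho_+ / rho_-` computed per replicate. The mean
#' and standard deviation over replicates are the ratio estimate and its
#' error. Replicates in which a stratum has fewer than 3 pairs, a correlation
#' is undefined (constant ranks), or `rho_-` is exactly 0 are discarded and
#' counted in `nDiscarded` rather than imputed.
#'
#' @param speed,theta numeric vectors of gated frame-pair speeds (mm/s) and
#'   defined movement angles (degrees); pairs with NA in either are dropped.
#' @param nReplicates bootstrap replicates (default 1000).
#' @param seed RNG seed for reproducibility.
#' @return a `RhoRatioEstimate` list: full-data `rhoPlus`, `rhoMinus`,
#'   bootstrap `ratioMean`, `ratioSd`, `replicates` (kept ratios),
#'   `nSample`, `nReplicates`, `nDiscarded`.
#' @export
bootstrapRhoRatio <- function(speed, theta, nReplicates = 1000, seed = 0) {
  ok <- !is.na(speed) & !is.na(theta)
  speed <- speed[ok]; theta <- theta[ok]
  n <- length(speed)
  if (sum(theta > 0) < 3L || sum(theta < 0) < 3L) {
    stop("each theta-sign stratum needs at least 3 pairs", call. = FALSE)
  }
  ratioOf <- function(s, th) {
    up <- th > 0; dn <- th < 0
    if (sum(up) < 3L || sum(dn) < 3L) return(NA_real_)
    rp <- .spearman(s[up], th[up])
    rm <- .spearman(s[dn], th[dn])
    if (is.na(rp) || is.na(rm) || rm == 0) return(NA_real_)
    rp / rm
  }
  reps <- .withSeed(seed, {
    vapply(seq_len(nReplicates), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      ratioOf(speed[i], theta[i])
    }, numeric(1))
  })
  kept <- reps[!is.na(reps)]
  structure(list(
    rhoPlus = .spearman(speed[theta > 0], theta[theta > 0]),
    rhoMinus = .spearman(speed[theta < 0], theta[theta < 0]),
    ratioMean = mean(kept), ratioSd = sd(kept),
    replicates = kept, nSample = n, nReplicates = nReplicates,
    nDiscarded = sum(is.na(reps))
  ), class = "RhoRatioEstimate")
}

#' @export
print.RhoRatioEstimate <- function(x, ...) {
  cat(sprintf(
    "RhoRatioEstimate: rho+ %.3f, rho- %.3f; ratio %.2f +/- %.2f (%d/%d replicates kept, N_sample %d)\n",
    x$rhoPlus, x$rhoMinus, x$ratioMean, x$ratioSd,
    length(x$replicates), x$nReplicates, x$nSample))
  invisible(x)
}

#' Nested per-group, per-fly behavioral summary
#'
#' Aggregates trajectories into the nested access structure used downstream:
#' `summary$Group[[g]]` holds the group `Names`, `ClimbCurves` (one
#' [climbingCurve()] per configured target height) and `Fly_no`, a list with
#' one entry per fly (flies pooled across trials, trial-major order), each
#' carrying `AveSpeed` (mean gated speed, mm/s), `AveAngle` (mean defined
#' angle, degrees), `SpdAngle` (the frame-pair speed-angle pairs), `Drops`,
#' `TurnRate` (turns/s) and `DistanceTraveled` (mean speed times video
#' duration, mm). Stationary and gated pairs contribute to neither average.
#'
#' @param groups named list; each group is a list of trials; each trial a
#'   list of trajectory data.frames (`x_mm`, `y_mm`).
#' @param config a `GeotaxisConfig` (gate, slip bounds, targets, frame rate).
#' @return a `GeotaxisSummary` list with element `Group`.
#' @export
summarizeGroups <- function(groups, config = geotaxisConfig()) {
  if (!length(groups)) stop("no groups supplied", call. = FALSE)
  dt <- 1 / config$frame_rate_hz
  out <- lapply(seq_along(groups), function(g) {
    trials <- groups[[g]]
    if (!length(trials) || !length(trials[[1]])) {
      stop("group '", names(groups)[g], "' is empty", call. = FALSE)
    }
    flies <- list()
    for (tr in seq_along(trials)) {
      for (f in seq_along(trials[[tr]])) {
        traj <- trials[[tr]][[f]]
        sa <- speedAngle(traj, gateMm = config$displacement_gate_mm, dt = dt)
        duration <- nrow(traj) * dt
        aveSpeed <- mean(sa$speed_mm_s, na.rm = TRUE)
        flies[[length(flies) + 1L]] <- list(
          Trial = tr, FlyInTrial = f,
          AveSpeed = aveSpeed,
          AveAngle = mean(sa$theta_deg, na.rm = TRUE),
          SpdAngle = sa[!is.na(sa$speed_mm_s) & !is.na(sa$theta_deg),
                        c("speed_mm_s", "theta_deg")],
          Drops = detectDrops(traj, config$slip_min_mm, config$slip_max_mm),
          TurnRate = turningRate(sa, dt, config$angle_tol_deg),
          DistanceTraveled = aveSpeed * duration
        )
      }
    }
    climb <- lapply(config$target_heights_mm, function(h) {
      climbingCurve(trials, h, dt, vialHeightMm = config$vial_height_mm)
    })
    names(climb) <- paste0(vapply(config$target_heights_mm,
                                  function(h) format(round(h, 2)), character(1)),
                           "mm")
    list(Names = names(groups)[g], ClimbCurves = climb, Fly_no = flies)
  })
  structure(list(Group = out), class = "GeotaxisSummary")
}

#' @export
print.GeotaxisSummary <- function(x, ...) {
  cat("GeotaxisSummary:", length(x$Group), "group(s)\n")
  for (g in x$Group) {
    cat(sprintf("  %s: %d flies, mean AveSpeed %.2f mm/s\n", g$Names,
                length(g$Fly_no),
                mean(vapply(g$Fly_no, `[[`, numeric(1), "AveSpeed"),
                     na.rm = TRUE)))
  }
  invisible(x)
}

#' Write a group summary to JSON
#'
#' Serializes the nested summary (climbing-curve step data, per-fly scalars
#' and speed-angle pairs) for downstream consumption.
#'
#' @param summary a `GeotaxisSummary`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeSummary <- function(summary, path) {
  ser <- lapply(summary$Group, function(g) {
    list(
      Names = g$Names,
      ClimbCurves = lapply(g$ClimbCurves, function(cc) {
        list(target_mm = cc$target, curve = cc$curve, crossings = cc$crossings)
      }),
      Fly_no = g$Fly_no
    )
  })
  jsonlite::write_json(list(Group = ser), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
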