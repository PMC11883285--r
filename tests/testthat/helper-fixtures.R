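# Shared fixtures and independent oracles, built in code at test time.

# Brute-force minimum-cost perfect matching by permutation enumeration.
# Independent oracle for the Hungarian solver; n <= 8 only.
bruteForceAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 8)
  best <- Inf
  bestPerm <- NULL
  permute <- function(chosen, remaining, acc) {
    if (acc >= best) return()  # admissible bound: costs are non-negative
    if (!length(remaining)) {
      best <<- acc
      bestPerm <<- chosen
      return()
    }
    i <- length(chosen) + 1L
    for (j in remaining) {
      permute(c(chosen, j), setdiff(remaining, j), acc + cost[i, j])
    }
  }
  permute(integer(0), seq_len(n), 0)
  list(cost = best, perm = bestPerm)
}

# Rank-and-Pearson Spearman oracle with average ranks for ties.
spearmanOracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  if (den == 0) NA_real_ else num / den
}

# Linear-interpolation percentile oracle (order-statistic interpolation).
percentileOracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# Small calibration table with known class geometry.
toyThresholds <- function() {
  df <- data.frame(
    area_px = c(50, 60, 80, 100, 150, 200, 170),
    major_axis_px = c(10, 10, 12, 14, 18, 20, 19),
    minor_axis_px = c(5, 6, 6, 7, 9, 12, 10),
    label = c("single", "single", "single", "single", "multi", "multi", "noise")
  )
  deriveThresholds(calibrationTable(df))
}

# Trajectory data.frame helper (physics convention, mm).
mkTraj <- function(x, y, dt = 1 / 30) {
  traj <- data.frame(x_mm = x, y_mm = y)
  attr(traj, "dt") <- dt
  traj
}

# A small rendered scene with a clean same-noise background: rendering the
# empty arena under the same seed reproduces the identical noise field, so
# segmentation isolates exactly the painted flies.
renderWithCleanBackground <- function(truth, params) {
  stack <- renderVideo(truth, params)
  empty <- groundTruth(matrix(0, 0, params$nFrames), matrix(0, 0, params$nFrames),
                       params)
  bgStack <- renderVideo(empty, params)
  list(stack = stack, background = bgStack@frames)
}

# Calibration-derived thresholds shared across tests (the renderer's fly
# geometry does not depend on arena size, so one calibration serves all).
sharedThresholds <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- deriveThresholds(calibrateFromSimulation(simParams()))
    }
    val
  }
})

# Small arena parameters for fast tests.
smallParams <- function(...) {
  args <- list(nFlies = 3, nFrames = 60, roiWidthPx = 80, roiHeightPx = 240)
  user <- list(...)
  args[names(user)] <- user
  do.call(simParams, args)
}
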