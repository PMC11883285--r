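test_that("the Kalman time update extrapolates the constant-velocity state", {
  tr <- newTrack(1, 10, 20, vx = 1, vy = -2)
  tr <- kalmanPredict(tr)
  expect_equal(tr$predicted, c(11, 18))
  still <- kalmanPredict(newTrack(1, 5, 7))
  expect_equal(still$predicted, c(5, 7))
  expect_error(kalmanPredict(list(m = 1:4)), "KalmanTrack")
})

test_that("predictions converge on noiseless linear motion", {
  cfg <- geotaxisConfig(measurement_noise_px = 0.05)
  tr <- newTrack(1, 0, 0, config = cfg)
  err <- NA
  for (t in 1:40) {
    tr <- kalmanPredict(tr)
    z <- c(t * 1.5, t * -0.7)          # exact line, 1.5 px/frame by -0.7
    err <- sqrt(sum((tr$predicted - z)^2))
    tr <- kalmanUpdate(tr, z)
  }
  expect_lt(err, 0.1)
})

test_that("cost entries combine prediction and previous-position distances", {
  # prediction overshoots to (0, 10); previous position is 2 px away from
  # the detection at the origin -> min rule keeps 2
  cost <- buildCostMatrix(predicted = c(0, 10), previous = c(0, 2),
                          detections = c(0, 0), con = 11)
  expect_equal(cost$real[1, 1], 2)
  expect_equal(dim(cost$cost), c(2L, 2L))

  # a detection coincident with the prediction costs zero
  cost <- buildCostMatrix(c(3, 4), c(10, 10), c(3, 4), con = 11)
  expect_equal(cost$real[1, 1], 0)

  # alternative combination rules
  cost <- buildCostMatrix(c(0, 10), c(0, 2), c(0, 0), con = 11, rule = "mean")
  expect_equal(cost$real[1, 1], 6)
  cost <- buildCostMatrix(c(0, 10), c(0, 2), c(0, 0), con = 11, rule = "pred")
  expect_equal(cost$real[1, 1], 10)

  # no tracks: the padded matrix is pure cost-of-non-assignment
  cost <- buildCostMatrix(matrix(numeric(0), 0, 2), matrix(numeric(0), 0, 2),
                          rbind(c(1, 2), c(3, 4)), con = 11)
  expect_equal(cost$cost, matrix(11, 2, 2))
})

test_that("assignment matches the brute-force optimum on worked examples", {
  mk <- function(real, con) {
    nT <- nrow(real); nD <- ncol(real)
    pred <- cbind(seq_len(nT) * 100, 0)
    det <- cbind(rep(0, nD), 0)
    cost <- buildCostMatrix(pred, pred, det, con = con)
    cost$real <- real
    cost$cost[seq_len(nT), seq_len(nD)] <- real
    cost$cost[nT + seq_len(nD), nD + seq_len(nT)] <- t(real)
    cost
  }
  # separable 2x2: diagonal pairing, total real cost 2
  cost <- mk(rbind(c(1, 10), c(10, 1)), con = 11)
  a <- solveAssignment(cost)
  expect_equal(a$pairs$track, 1:2)
  expect_equal(a$pairs$detection, 1:2)
  expect_equal(sum(cost$real[cbind(a$pairs$track, a$pairs$detection)]), 2)
  expect_equal(a$totalCost, bruteForceAssignment(cost$cost)$cost)

  # a lone pair at distance 12 with CON = 11: double non-assignment (22)
  # beats assignment (2 x 12 via the transposed block); both go unassigned
  cost <- mk(matrix(12, 1, 1), con = 11)
  a <- solveAssignment(cost)
  expect_equal(nrow(a$pairs), 0L)
  expect_equal(a$unassignedTracks, 1L)
  expect_equal(a$unassignedDetections, 1L)
  expect_equal(a$totalCost, bruteForceAssignment(cost$cost)$cost)

  # distance 5 with CON = 11 assigns
  cost <- mk(matrix(5, 1, 1), con = 11)
  a <- solveAssignment(cost)
  expect_equal(a$pairs$track, 1L)

  expect_error(solveAssignment(structure(list(cost = matrix(c(1, NA, 1, 1), 2),
                                              nTracks = 1L, nDetections = 1L),
                                         class = "CostMatrix")), "non-finite")
})

test_that("assignment equals the brute-force optimum on random padded matrices", {
  set.seed(42)
  for (i in 1:60) {
    nT <- sample(0:3, 1); nD <- sample(0:3, 1)
    if (nT + nD == 0) next
    pred <- matrix(runif(nT * 2, 0, 50), ncol = 2)
    prev <- pred + matrix(rnorm(nT * 2), ncol = 2)
    det <- matrix(runif(nD * 2, 0, 50), ncol = 2)
    cost <- buildCostMatrix(pred, prev, det, con = runif(1, 1, 20))
    a <- solveAssignment(cost)
    expect_equal(a$totalCost, bruteForceAssignment(cost$cost)$cost,
                 tolerance = 1e-9)
  }
})

test_that("track bookkeeping handles surplus, new and reappearing flies", {
  cfg <- geotaxisConfig(n_flies = 7L)
  step <- function(tracks, det) {
    tracks <- lapply(tracks, kalmanPredict)
    pred <- do.call(rbind, lapply(tracks, `[[`, "predicted"))
    if (is.null(pred)) pred <- matrix(numeric(0), 0, 2)
    prev <- do.call(rbind, lapply(tracks, `[[`, "lastKnown"))
    if (is.null(prev)) prev <- matrix(numeric(0), 0, 2)
    cost <- buildCostMatrix(pred, prev, det, con = cfg$con)
    updateTracks(tracks, det, solveAssignment(cost), cfg$n_flies, cfg)
  }

  # 7 established tracks, 7 nearby detections plus 1 stray: stray discarded
  tracks <- lapply(1:7, function(i) newTrack(i, i * 15, 100, config = cfg))
  det <- rbind(cbind(1:7 * 15, 100.5), c(60, 400))
  tracks <- step(tracks, det)
  expect_length(tracks, 7L)
  expect_true(all(vapply(tracks, `[[`, logical(1), "seen")))

  # 5 tracks with 7 detections: two new tracks are founded
  tracks5 <- lapply(1:5, function(i) newTrack(i, i * 15, 100, config = cfg))
  tracks5 <- step(tracks5, det)
  expect_length(tracks5, 7L)

  # an occluded fly reappearing near its last known position resumes its id
  tracks <- lapply(1:2, function(i) newTrack(i, i * 50, 100,
                                             config = geotaxisConfig(n_flies = 2L)))
  cfg2 <- geotaxisConfig(n_flies = 2L)
  stepN <- function(tracks, det) {
    tracks <- lapply(tracks, kalmanPredict)
    pred <- do.call(rbind, lapply(tracks, `[[`, "predicted"))
    prev <- do.call(rbind, lapply(tracks, `[[`, "lastKnown"))
    cost <- buildCostMatrix(pred, prev, det, con = cfg2$con)
    updateTracks(tracks, det, solveAssignment(cost), cfg2$n_flies, cfg2)
  }
  for (i in 1:5) tracks <- stepN(tracks, matrix(c(50, 100), 1))  # fly 2 hidden
  expect_equal(tracks[[2]]$framesInvisible, 5L)
  expect_equal(tracks[[2]]$lastKnown, c(100, 100))
  tracks <- stepN(tracks, rbind(c(50, 100), c(101, 102)))  # reappears nearby
  expect_equal(tracks[[2]]$framesInvisible, 0L)
  expect_equal(tracks[[2]]$pos, c(101, 102))
})

test_that("a long-lost track is revived by a far surplus detection", {
  cfg <- geotaxisConfig(n_flies = 2L, max_invisible_frames = 3L)
  tracks <- lapply(1:2, function(i) newTrack(i, i * 40, 50, config = cfg))
  stepN <- function(tracks, det) {
    tracks <- lapply(tracks, kalmanPredict)
    pred <- do.call(rbind, lapply(tracks, `[[`, "predicted"))
    prev <- do.call(rbind, lapply(tracks, `[[`, "lastKnown"))
    cost <- buildCostMatrix(pred, prev, det, con = cfg$con)
    updateTracks(tracks, det, solveAssignment(cost), cfg$n_flies, cfg)
  }
  # fly 2 vanishes and a distant detection appears every frame (fly after a
  # fall); for the first two frames it is discarded, on the third the lost
  # track is relocated onto it
  for (i in 1:2) {
    tracks <- stepN(tracks, rbind(c(40, 50), c(75, 300)))
    expect_equal(tracks[[2]]$pos, c(80, 50))   # still coasting
  }
  tracks <- stepN(tracks, rbind(c(40, 50), c(75, 300)))
  expect_equal(tracks[[2]]$pos, c(75, 300))
  expect_equal(tracks[[2]]$id, 2L)
  expect_equal(tracks[[2]]$framesInvisible, 0L)
})

test_that("finalization seeds missing flies at the vial bottom, reproducibly", {
  cfg <- geotaxisConfig(n_flies = 3L, rng_seed = 11L)
  emptyDet <- replicate(20, data.frame(x_px = numeric(0), y_px = numeric(0)),
                        simplify = FALSE)
  cm <- trackDetections(emptyDet, cfg, roiDim = c(200, 60))
  expect_equal(nFlies(cm), 3L)
  expect_equal(nFrames(cm), 20L)
  # constant tracks within the bottom 5% of the ROI height
  expect_true(all(apply(coordinates(cm)$y, 1, function(r) length(unique(r)) == 1)))
  expect_true(all(coordinates(cm)$y >= 0.95 * 199))
  expect_true(all(coordinates(cm)$x >= 0 & coordinates(cm)$x <= 59))
  expect_false(any(visibility(cm)))
  cm2 <- trackDetections(emptyDet, cfg, roiDim = c(200, 60))
  expect_identical(coordinates(cm), coordinates(cm2))
})

test_that("one undetectable fly yields a bottom-seeded row next to real tracks", {
  cfg <- geotaxisConfig(n_flies = 3L)
  det <- lapply(1:30, function(t) {
    data.frame(x_px = c(20, 40), y_px = c(150 - t, 150 - 2 * t))
  })
  cm <- trackDetections(det, cfg, roiDim = c(200, 60))
  expect_equal(nFlies(cm), 3L)
  expect_true(all(visibility(cm)[1:2, ]))
  expect_false(any(visibility(cm)[3, ]))
  expect_true(all(coordinates(cm)$y[3, ] >= 0.95 * 199))
})

test_that("every finalized matrix has n_flies rows and finite coordinates", {
  set.seed(99)
  for (rep in 1:5) {
    nfly <- sample(1:4, 1)
    cfg <- geotaxisConfig(n_flies = nfly)
    det <- lapply(1:25, function(t) {
      k <- sample(0:(nfly + 1), 1)
      data.frame(x_px = runif(k, 0, 59), y_px = runif(k, 0, 199))
    })
    cm <- trackDetections(det, cfg, roiDim = c(200, 60))
    expect_equal(dim(coordinates(cm)$x), c(nfly, 25L))
    expect_true(all(is.finite(coordinates(cm)$x)))
    expect_true(all(is.finite(coordinates(cm)$y)))
  }
})

test_that("crossing-free constant-velocity flies are tracked exactly", {
  p <- smallParams(nFrames = 50, noiseSd = 0.005)
  t <- seq_len(50) - 1
  x <- rbind(20 + 0.1 * t, rep(40, 50), 60 - 0.1 * t)
  y <- rbind(200 - 2 * t, 170 - 1.5 * t, 230 - 2.5 * t)
  truth <- groundTruth(x, y, p)
  stack <- renderVideo(truth, p)
  thr <- sharedThresholds()
  cfg <- geotaxisConfig(n_flies = 3L)
  cm <- trackVideo(stack, thr, cfg)
  report <- evaluateTracking(truth, cm, tolPx = 10)
  expect_equal(report@switchFraction, 0)
  expect_equal(report@fractionCorrect, 1)
  expect_lt(max(report@errorsPx), 1)
})
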