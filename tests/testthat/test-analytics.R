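test_that("pixel coordinates convert to mm with the vial-bottom origin", {
  x <- matrix(c(0, 9.7, 48.5), 1, 3)
  y <- matrix(c(680, 680 - 9.7, 340), 1, 3)
  cm <- coordinateMatrix(x, y)
  trajs <- toPhysical(cm, roiHeightPx = 680, pxPerMm = 4.85)
  traj <- trajs[[1]]
  expect_equal(traj$y_mm[1], 0)                     # ROI bottom is height zero
  expect_equal(traj$y_mm[2], 2)                     # 9.7 px is 2 mm
  expect_equal(traj$x_mm[2], 2)                     # x is scaled, not flipped
  expect_equal(diff(traj$x_mm)[1], diff(x[1, ])[1] / 4.85)
  expect_error(toPhysical(cm, 680, pxPerMm = 0), "positive")
})

test_that("speed and angle follow the frame-pair displacement equations", {
  dt <- 1 / 30
  traj <- mkTraj(c(0, 0.9, 0.9, -0.1, -0.1, 2.9), c(0, 1.2, 1.2, 1.2, 5.2, 1.2))
  sa <- speedAngle(traj, gateMm = 4, dt = dt)
  # 3-4-5 triangle: dr = 1.5 mm in 1/30 s -> 45 mm/s at atan2(1.2, 0.9)
  expect_equal(sa$dr_mm[1], 1.5)
  expect_equal(sa$speed_mm_s[1], 45)
  expect_equal(sa$theta_deg[1], atan2(1.2, 0.9) * 180 / pi)
  expect_equal(sa$theta_deg[1], 53.13, tolerance = 1e-4)
  # stationary pair: zero speed, undefined angle
  expect_equal(sa$speed_mm_s[2], 0)
  expect_true(is.na(sa$theta_deg[2]))
  # leftward movement is indistinguishable from rightward
  expect_equal(sa$theta_deg[3], 0)
  # exactly 4 mm: the gate is inclusive, the pair carries no speed or angle
  expect_equal(sa$dr_mm[4], 4)
  expect_true(sa$gated[4])
  expect_true(is.na(sa$speed_mm_s[4]))
  expect_true(is.na(sa$theta_deg[4]))
  # 3-4-5 again but descending and leftward: same speed, negative angle
  expect_equal(sa$dr_mm[5], 5)
  expect_true(sa$gated[5])

  diagonal <- mkTraj(c(0, -1), c(0, 1))
  expect_equal(speedAngle(diagonal, dt = 1 / 30)$theta_deg, 45)
  expect_error(speedAngle(mkTraj(0, 0), dt = dt), "2 frames")
})

test_that("movement angles span (-90, 90] with vertical extremes", {
  up <- speedAngle(mkTraj(c(0, 0), c(0, 1)), dt = 1 / 30)
  down <- speedAngle(mkTraj(c(0, 0), c(1, 0)), dt = 1 / 30)
  expect_equal(up$theta_deg, 90)
  expect_equal(down$theta_deg, -90)
})

test_that("turning rate counts non-zero angle changes per second", {
  dt <- 1 / 30
  # constant direction: no turns
  straight <- mkTraj(seq(0, 3, by = 0.1), seq(0, 3, by = 0.1))
  expect_equal(turningRate(speedAngle(straight, dt = dt), dt), 0)

  # 31 frames over 1 s alternating +/-45 degrees: 30 pairs, 29 changes
  n <- 31
  y <- cumsum(c(0, rep(c(0.5, -0.5), length.out = n - 1)))
  zig <- mkTraj(seq_len(n) * 0.5, y)
  sa <- speedAngle(zig, dt = dt)
  expect_equal(sort(unique(sa$theta_deg)), c(-45, 45))
  expect_equal(turningRate(sa, dt), 29)

  # an undefined angle breaks the chain: no change is counted across it
  brokenY <- c(0, 1, 2, 2, 3, 2)        # pause at pair 3
  broken <- mkTraj(rep(0, 6), brokenY)
  sa <- speedAngle(broken, dt = dt)
  expect_true(is.na(sa$theta_deg[3]))
  # pairs 1-2 equal (no turn); pairs 4-5 differ (one turn); 3 breaks chains
  expect_equal(turningRate(sa, dt) * (nrow(sa) * dt), 1)
})

test_that("climbing curves count only the first crossing per fly", {
  dt <- 1 / 30
  # crosses 70 mm at frame 60 (t = 2 s), dips below, re-crosses later
  y <- c(seq(0, 69, length.out = 60), 71, 72, 69, 65, 71, 72)
  traj <- mkTraj(rep(1, length(y)), y)
  cc <- climbingCurve(list(list(traj)), 70, dt = dt)
  expect_equal(nrow(cc$crossings), 1L)
  expect_equal(cc$crossings$time_s, 60 * dt)
  expect_equal(cc$curve$mean, 1)

  # nobody crosses: a flat zero curve
  low <- mkTraj(rep(1, 10), rep(5, 10))
  cc0 <- climbingCurve(list(list(low)), 70, dt = dt)
  expect_equal(nrow(cc0$crossings), 0L)
  expect_equal(nrow(cc0$curve), 0L)

  expect_error(climbingCurve(list(list(low)), 150, dt = dt,
                             vialHeightMm = 140), "exceeds")
})

test_that("trial averaging steps by 1/N_trials at each crossing time", {
  dt <- 1 / 30
  cross_at <- function(t) {
    n <- 150
    y <- rep(0, n); y[(t * 30 + 1):n] <- 80
    mkTraj(rep(1, n), y)
  }
  trials <- list(list(cross_at(1)), list(cross_at(3)))
  cc <- climbingCurve(trials, 70, dt = dt)
  expect_equal(cc$curve$time_s, c(1, 3))
  expect_equal(cc$curve$mean, c(0.5, 1.0))
  # terminal value never exceeds the per-trial fly count
  expect_lte(max(cc$curve$mean), 1)
  # averaging identical trials reproduces the single-trial staircase
  same <- climbingCurve(list(list(cross_at(2)), list(cross_at(2))), 70, dt = dt)
  expect_equal(same$curve$mean, 1)
  expect_equal(same$curve$sem, 0)
})

test_that("slip/fall boundaries are inclusive at one and three body lengths", {
  mk <- function(drop, from = 100) mkTraj(c(0, 0), c(from, from - drop))
  expect_equal(detectDrops(mk(12.0))$kind, "slip")   # three body lengths: slip
  expect_equal(detectDrops(mk(12.1))$kind, "fall")
  expect_equal(detectDrops(mk(4.5))$kind, "slip")
  expect_equal(nrow(detectDrops(mk(4.4))), 0L)
  full <- detectDrops(mkTraj(c(0, 0), c(20, 0)))     # drop to the very bottom
  expect_equal(full$kind, "fall")
  expect_equal(full$ratio, 1.0)
  expect_equal(full$pre_drop_height_mm, 20)
})

test_that("slip/fall pairs are always excluded from the speed-angle series", {
  set.seed(5)
  for (i in 1:20) {
    n <- 60
    y <- cumsum(rnorm(n, 0.3, 3))
    y <- pmax(pmin(y, 140), 0)
    traj <- mkTraj(cumsum(rnorm(n, 0, 0.5)), y)
    sa <- speedAngle(traj, gateMm = 4, dt = 1 / 30)
    drops <- detectDrops(traj)
    if (nrow(drops)) {
      # a drop is at least 4.5 mm, beyond the 4 mm gate by construction
      expect_true(all(sa$gated[drops$frame]))
      expect_true(all(is.na(sa$speed_mm_s[drops$frame])))
    }
  }
})

test_that("Spearman matches a rank-and-Pearson oracle on tied small samples", {
  set.seed(31)
  for (i in 1:300) {
    n <- sample(3:8, 1)
    x <- sample(1:4, n, replace = TRUE)   # heavy ties
    y <- sample(1:4, n, replace = TRUE)
    ours <- geotrack:::.spearman(x, y)
    oracle <- spearmanOracle(x, y)
    if (is.na(oracle)) expect_true(is.na(ours)) else expect_equal(ours, oracle)
  }
})

test_that("the bootstrapped correlation ratio is exact under perfect monotonicity", {
  theta <- c(seq(-80, -10, length.out = 30), seq(10, 80, length.out = 30))
  speed <- c(seq(1, 30, length.out = 30), seq(1, 30, length.out = 30))
  est <- bootstrapRhoRatio(speed, theta, nReplicates = 50, seed = 1)
  expect_equal(est$rhoPlus, 1)
  expect_equal(est$rhoMinus, 1)
  expect_equal(est$ratioMean, 1)
  expect_equal(est$ratioSd, 0)
  expect_equal(est$nSample, 60L)
})

test_that("the bootstrap is deterministic under a fixed seed and logs discards", {
  set.seed(2)
  theta <- runif(200, -90, 90)
  speed <- runif(200, 1, 40)
  a <- bootstrapRhoRatio(speed, theta, nReplicates = 100, seed = 7)
  b <- bootstrapRhoRatio(speed, theta, nReplicates = 100, seed = 7)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$ratioMean, b$ratioMean)
  expect_equal(length(a$replicates) + a$nDiscarded, 100L)
  expect_error(bootstrapRhoRatio(1:10, rep(40, 10)), "stratum")
})

test_that("planted rank correlations of 0.6 and 0.3 give a ratio near 2", {
  # Gaussian copula with rank-correlation calibration: a bivariate normal
  # with Pearson r = 2*sin(pi*rho_s/6) has Spearman correlation rho_s
  rp <- function(rs) 2 * sin(pi * rs / 6)
  gen <- function(n, r, sign) {
    z1 <- rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    list(speed = 40 * pnorm(z1), theta = sign * 90 * pnorm(sign * z2))
  }
  set.seed(123)
  up <- gen(5000, rp(0.6), 1)
  dn <- gen(5000, rp(0.3), -1)
  speed <- c(up$speed, dn$speed)
  theta <- c(up$theta, dn$theta)
  est <- bootstrapRhoRatio(speed, theta, nReplicates = 200, seed = 99)
  expect_equal(est$rhoPlus, 0.6, tolerance = 0.05)
  expect_equal(est$rhoMinus, 0.3, tolerance = 0.1)
  expect_lt(abs(est$ratioMean - 2), 3 * est$ratioSd + 0.05)
})

test_that("group summaries expose the nested per-fly access structure", {
  dt <- 1 / 30
  n <- 300                               # a 10 s trial at 30 Hz
  up <- mkTraj(rep(3, n), seq(0, by = 10 * dt, length.out = n))
  grp <- list(wild = list(list(up, up)))
  cfg <- geotaxisConfig(n_flies = 2L, target_heights_mm = c(70, 140))
  s <- summarizeGroups(grp, cfg)
  fly2 <- s$Group[[1]]$Fly_no[[2]]
  expect_equal(fly2$AveSpeed, 10)
  expect_equal(fly2$AveAngle, 90)
  expect_equal(fly2$DistanceTraveled, 10 * n * dt, tolerance = 1e-9)
  expect_equal(fly2$TurnRate, 0)
  expect_equal(nrow(fly2$Drops), 0L)
  # two identical flies: the group mean equals the individual value
  speeds <- vapply(s$Group[[1]]$Fly_no, `[[`, numeric(1), "AveSpeed")
  expect_equal(mean(speeds), 10)
  expect_equal(s$Group[[1]]$Names, "wild")
  expect_length(s$Group[[1]]$ClimbCurves, 2L)
  expect_error(summarizeGroups(list(empty = list()), cfg), "empty")
})

test_that("group summaries serialize to JSON", {
  dt <- 1 / 30
  up <- mkTraj(rep(3, 60), seq(0, by = 10 * dt, length.out = 60))
  s <- summarizeGroups(list(g = list(list(up))), geotaxisConfig(n_flies = 1L))
  path <- withr::local_tempfile(fileext = ".json")
  writeSummary(s, path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(j$Group[[1]]$Names, "g")
  expect_equal(j$Group[[1]]$Fly_no[[1]]$AveSpeed, 10, tolerance = 1e-9)
  expect_equal(j$Group[[1]]$ClimbCurves[[1]]$target_mm, 140 / 3)
})
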