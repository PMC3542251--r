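test_that("the intensity function encodes the three archetypes", {
  lam3 <- intensityFunction(SimulationConfig(3))
  expect_equal(lam3(seq(0, 4000, by = 100)), rep(1.96, 41))

  lam2 <- intensityFunction(SimulationConfig(2))
  v <- seq(0, 4000, by = 5)
  expect_equal(v[which.max(lam2(v))], 1600)   # mode 400 um outside
  expect_equal(lam2(1600), lam2(0) + 6.7, tolerance = 1e-6)
  # asymmetric flanks: slow rise outside, fast decline inside
  expect_gt(lam2(1600 - 200) - lam2(0), lam2(1600 + 200) - lam2(0) + 1)

  lam1 <- intensityFunction(SimulationConfig(1, lambdaOut = 2,
                                             lambdaIn = 2))
  expect_equal(lam1(c(100, 3900)), c(2, 2))
  lam1b <- intensityFunction(SimulationConfig(1))
  expect_equal(lam1b(1999), 1.5)
  expect_equal(lam1b(2000), 4.61)
})

test_that("profile sampling is Poisson around the intensity", {
  cfg <- SimulationConfig(3, lambdaOut = 2)
  sp <- simulateProfile(cfg, seed = 77)
  expect_equal(sp$true_pattern, 3L)
  m <- mean(profileDensity(sp$profile))
  expect_gt(m, 1.8); expect_lt(m, 2.2)   # 99% Poisson CI at n = 800
  sp2 <- simulateProfile(cfg, seed = 77)
  expect_identical(profileDensity(sp$profile),
                   profileDensity(sp2$profile))
  zero <- simulateProfile(SimulationConfig(3, lambdaOut = 0), seed = 1)
  expect_equal(sum(profileDensity(zero$profile)), 0)
})

test_that("mean sampled profile converges to the intensity function", {
  cfg <- SimulationConfig(2)
  lam <- intensityFunction(cfg)
  v <- seq(0, 3995, by = 5)
  acc <- numeric(800)
  nrep <- 300
  for (s in 1:nrep)
    acc <- acc + profileDensity(simulateProfile(cfg, seed = 9000 + s)$profile)
  avg <- acc / nrep
  se <- sqrt(lam(v) / nrep)
  expect_true(all(abs(avg - lam(v)) <= pmax(3 * se, 1e-9) + 0.05))
})

test_that("point fields have Poisson-consistent totals", {
  cfg <- SimulationConfig(2)
  lam <- intensityFunction(cfg)
  expected <- sum(lam(seq(0, 3995, by = 5)))   # W = 1000 um
  n <- nrow(simulatePoints(cfg, seed = 5))
  expect_lt(abs(n - expected), 3 * sqrt(expected))
  none <- simulatePoints(SimulationConfig(3, lambdaOut = 0), seed = 5)
  expect_equal(nrow(none), 0)
})

test_that("rendered slides carry a faithful ground truth", {
  dims <- c(width = 250, length = 1200)
  truth <- simulateSlide(SimulationConfig(3), seed = 19, roiDims = dims)
  cc <- truthCentroids(truth)
  expect_true(all(cc[, 1] >= 0 & cc[, 1] <= 1200 &
                  cc[, 2] >= 0 & cc[, 2] <= 250))
  expect_equal(truth@truePattern, 3L)
  # empty config renders no positive stain at all
  blank <- simulateSlide(SimulationConfig(3, lambdaOut = 0), seed = 3,
                         roiDims = dims)
  expect_equal(nrow(truthCentroids(blank)), 0)
  expect_equal(sum(stainMask(truthImage(blank))), 0)
})

test_that("the detection round-trip recovers the simulated density shape", {
  dims <- c(width = 400, length = 4000)
  cfg <- SimulationConfig(2)
  truth <- simulateSlide(cfg, seed = 29, roiDims = dims)
  roi <- buildROI(truth@front, arcPosition = 200, width = 400)
  dets <- detectCells(truthImage(truth), roi)
  prof <- smoothProfile(toDensity(binCounts(dets, roi), roi), 21)
  lam <- intensityFunction(cfg)
  expect_gt(cor(profileDensity(prof), lam(seq(0, 3995, by = 5))), 0.9)
})

test_that("cohort draws follow the mixture and carry per-patient truth", {
  co <- simulateCohort(1000, seed = 61)
  expect_length(co$profiles, 1000)
  frac <- tabulate(co$true_pattern, 3) / 1000
  expect_true(all(abs(frac - c(0.21, 0.61, 0.18)) <= 0.03))
  all1 <- simulateCohort(50, seed = 62, mixture = c(1, 0, 0))
  expect_true(all(all1$true_pattern == 1L))
  none <- simulateCohort(0, seed = 63)
  expect_length(none$profiles, 0)
  expect_error(simulateCohort(10, seed = 1, mixture = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("TMA core sampling recovers a homogeneous calibration density", {
  # homogeneous field at 612 cells/mm^2 (= 3.06 per 5000 um^2)
  cfg <- SimulationConfig(3, lambdaOut = 3.06)
  est <- numeric(100)
  for (s in 1:100) {
    pts <- simulatePoints(cfg, seed = 300 + s)
    est[s] <- simulateTMADensity(pts, region = c(2000, 4000, 0, 1000),
                                 seed = 600 + s)$mean_density_mm2
  }
  se <- sd(est) / sqrt(100)
  expect_lt(abs(mean(est) - 612), 2 * se + 15)
  zero <- simulateTMADensity(matrix(numeric(0), 0, 2),
                             region = c(0, 2000, 0, 1000), seed = 1)
  expect_equal(zero$mean_density_mm2, 0)
})

test_that("TMA anchors are recovered from pattern point fields", {
  # the x0.005 mm^2-to-5000 um^2 conversion: pattern-1 tumors were
  # calibrated at 4.61 cells/5000 um^2 = 922 cells/mm^2, pattern 3 at
  # 1.96 = 392; core sampling of the tumor region recovers both
  for (anchor in list(c(1, 922), c(3, 392))) {
    est <- numeric(40)
    for (s in 1:40) {
      pts <- simulatePoints(SimulationConfig(anchor[1]), seed = 800 + s)
      est[s] <- simulateTMADensity(pts, region = c(2000, 4000, 0, 1000),
                                   seed = 900 + s)$mean_density_mm2
    }
    expect_equal(mean(est), anchor[2], tolerance = 0.05)
  }
})

test_that("single cores are noisier than whole-rectangle quantification", {
  cfg <- SimulationConfig(2)
  core <- roiTotal <- numeric(60)
  for (s in 1:60) {
    pts <- simulatePoints(cfg, seed = 1500 + s)
    core[s] <- simulateTMADensity(pts, region = c(2000, 4000, 0, 1000),
                                  nCores = 1,
                                  seed = 1600 + s)$mean_density_mm2
    roiTotal[s] <- nrow(pts) / 4   # whole 4 mm^2 rectangle, per mm^2
  }
  expect_gt(var(core), var(roiTotal))
})
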