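test_that("a uniform counterstain image yields an empty mask", {
  px <- array(0, dim = c(50, 50, 3))
  px[, , 1] <- 90; px[, , 2] <- 100; px[, , 3] <- 180
  expect_equal(sum(stainMask(IHCImage(px, 1))), 0)
})

test_that("a rendered brown disc is recovered with its analytic area", {
  img <- discImage(c(50, 50), radius = 3.5, nx = 200, ny = 200, mpp = 0.5)
  mask <- stainMask(img)
  labels <- splitTouching(mask, img@mpp)
  expect_equal(max(labels), 1)
  expect_equal(sum(mask) * img@mpp^2, pi * 3.5^2, tolerance = 0.15)
})

test_that("non-overlapping cells come out as one component each", {
  centers <- as.matrix(expand.grid(seq(10, 190, by = 20),
                                   seq(10, 190, by = 20)))  # 100 cells
  img <- discImage(centers, nx = 200, ny = 200)
  labels <- splitTouching(stainMask(img), 1)
  expect_equal(max(labels), 100)
})

test_that("watershed splits touching discs but not single ones", {
  one <- discImage(c(30, 30), nx = 120, ny = 120, mpp = 0.5)
  expect_equal(max(splitTouching(stainMask(one), 0.5)), 1)
  two <- discImage(rbind(c(30, 30), c(35, 30)), nx = 120, ny = 120,
                   mpp = 0.5)   # overlapping pair, centers 5 um apart
  expect_equal(max(splitTouching(stainMask(two), 0.5)), 2)
  empty <- matrix(0L, 20, 20)
  expect_equal(max(splitTouching(empty, 1)), 0)
})

test_that("size filtering drops debris and keeps lymphocyte-scale objects", {
  lab <- matrix(0L, 40, 40)
  lab[1:2, 1] <- 1L                 # 2 um^2: below the minimum
  expect_equal(nrow(sizeFilter(lab, 1)), 0)
  lab2 <- matrix(0L, 40, 40)
  lab2[11:15, 11:18] <- 1L          # 40 um^2: inside the bounds
  out <- sizeFilter(lab2, 1)
  expect_equal(nrow(out), 1)
  expect_equal(out$area_um2, 40)
  expect_equal(out$x_um, mean((11:15) - 0.5))
  lab3 <- matrix(0L, 40, 40)
  lab3[11:30, 11:30] <- 1L          # 400 um^2 merged debris: above max
  expect_equal(nrow(sizeFilter(lab3, 1)), 0)
})

test_that("detection on a synthetic slide recovers the ground truth", {
  # ~300 true cells on a narrow rectangle at default generator settings
  dims <- c(width = 200, length = 4000)
  truth <- simulateSlide(SimulationConfig(3), seed = 11, roiDims = dims)
  roi <- buildROI(truth@front, arcPosition = 100, width = 200)
  expect_gt(nrow(truthCentroids(truth)), 250)
  dets <- detectCells(truthImage(truth), roi)
  m <- matchCentroids(dets, truthCentroids(truth))
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  # determinism: byte-identical list on a second run
  expect_identical(dets, detectCells(truthImage(truth), roi))
})

test_that("a pure-counterstain rectangle yields no detections", {
  px <- array(0, dim = c(300, 120, 3))
  px[, , 1] <- 200; px[, , 2] <- 205; px[, , 3] <- 230
  roi <- RectangleROI(anchor = c(150, 50), normal = c(1, 0), width = 100,
                      length = 200)
  expect_equal(nrow(detectCells(IHCImage(px, 1), roi)), 0)
})

test_that("a rectangle outside the image is rejected", {
  img <- discImage(c(50, 50))
  roi <- RectangleROI(anchor = c(50, 50), normal = c(1, 0), width = 50,
                      length = 500)
  expect_error(detectCells(img, roi), "exceeds image bounds")
})

test_that("raising the red threshold never adds mask pixels", {
  set.seed(3)
  px <- array(runif(30 * 30 * 3, 0, 255), dim = c(30, 30, 3))
  img <- IHCImage(px, 1)
  sizes <- vapply(c(40, 80, 120, 160, 200), function(r)
    sum(stainMask(img, DetectionParams(redIntensity = r))), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("detections map onto themselves under a quarter-turn rotation", {
  dims <- c(width = 200, length = 400)
  truth <- simulateSlide(SimulationConfig(3), seed = 23, roiDims = dims)
  img <- truthImage(truth)
  roi <- buildROI(truth@front, arcPosition = 100, width = 200,
                  length = 400)
  dets <- detectCells(img, roi)
  # rotate the raster 90 degrees clockwise on screen: (i, j) -> (ny+1-j, i)
  d <- dim(img@pixels)
  rot <- array(0, dim = c(d[2], d[1], 3))
  for (ch in 1:3) rot[, , ch] <- t(img@pixels[, , ch])[d[2]:1, ]
  imgR <- IHCImage(rot, img@mpp)
  W <- d[2] * img@mpp
  rotPt <- function(p) cbind(W - p[, 2], p[, 1])
  anchorR <- as.vector(rotPt(matrix(roi@anchor, 1)))
  roiR <- RectangleROI(anchorR, c(0, 1), width = 200, length = 400)
  detsR <- detectCells(imgR, roiR)
  back <- cbind(detsR$y_um, W - detsR$x_um)
  m <- matchCentroids(cbind(dets$x_um, dets$y_um), back, radius = 1)
  expect_equal(m$n_matched, nrow(dets))
  expect_equal(nrow(detsR), nrow(dets))
})
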