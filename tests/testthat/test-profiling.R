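detFrame <- function(xy) data.frame(x_um = xy[, 1], y_um = xy[, 2],
                                    area_um2 = 40, intensity = 160)

test_that("cells land in the segment containing their axial position", {
  roi <- horizontalROI()
  # a cell exactly on the front: v = 2000, bin index 401 (1-based)
  d <- detFrame(matrix(uvToPoint(0, 2000, roi), 1))
  counts <- binCounts(d, roi)
  expect_equal(length(counts), 800)
  expect_equal(counts[401], 1)
  expect_equal(sum(counts), 1)
  # the closed inner edge: v = 4000 exactly joins the final bin
  d2 <- detFrame(matrix(uvToPoint(0, 4000, roi), 1))
  expect_equal(binCounts(d2, roi)[800], 1)
  # conservation on random cells
  set.seed(8)
  d3 <- detFrame(uvToPoint(runif(50, -500, 500), runif(50, 0, 4000), roi))
  expect_equal(sum(binCounts(d3, roi)), 50)
})

test_that("density standardizes counts to a 1 mm analysis width", {
  roi <- horizontalROI()
  counts <- integer(800); counts[10] <- 3L
  p <- toDensity(counts, roi)
  expect_equal(profileDensity(p)[10], 3.0)   # W = 1000: density == count
  expect_equal(p@widthUsed, 1000)
  roi500 <- horizontalROI(width = 500)
  expect_equal(profileDensity(toDensity(counts, roi500))[10], 6.0)
  expect_equal(profileDensity(toDensity(integer(800), roi)),
               rep(0, 800))
})

test_that("merging curves takes the per-bin mean", {
  p2 <- flatProfile(2); p4 <- flatProfile(4)
  m <- mergeProfiles(list(p2, p4))
  expect_equal(profileDensity(m), rep(3, 800))
  expect_equal(m@nRectangles, 2)
  same <- mergeProfiles(list(p2, p2, p2))
  expect_equal(profileDensity(same), profileDensity(p2))
  one <- mergeProfiles(list(p4))
  expect_equal(profileDensity(one), profileDensity(p4))
  expect_equal(one@nRectangles, 1)
  short <- DensityProfile(rep(1, 400), binEdges = seq(0, 2000, by = 5))
  expect_error(mergeProfiles(list(p2, short)), "same bin grid")
})

test_that("merging commutes with density standardization", {
  roi <- horizontalROI()
  set.seed(4)
  c1 <- rpois(800, 2); c2 <- rpois(800, 5)
  viaDensity <- mergeProfiles(list(toDensity(c1, roi), toDensity(c2, roi)))
  viaCounts <- toDensity((c1 + c2) / 2, roi)
  expect_equal(profileDensity(viaDensity), profileDensity(viaCounts))
})

test_that("smoothing is a truncated centered moving average", {
  p <- bumpProfile()
  expect_equal(profileDensity(smoothProfile(p, 1)), profileDensity(p))
  expect_equal(profileDensity(smoothProfile(flatProfile(2.5), 21)),
               rep(2.5, 800))
  imp <- flatProfile(0)
  imp@density[400] <- 21
  sm <- smoothProfile(imp, 21)
  expect_equal(profileDensity(sm)[390:410], rep(1, 21))
  expect_equal(profileDensity(sm)[389], 0)
  expect_error(smoothProfile(p, 10), "odd")
})

test_that("max/min ratio measures heterogeneity with a zero floor", {
  expect_equal(minmaxRatio(flatProfile(3))$ratio, 1)
  ramp <- DensityProfile(seq(2, 10, length.out = 800))
  r <- minmaxRatio(ramp, window = c(2000, 4000), windowBins = 1)
  expect_equal(r$ratio, max(ramp@density) / ramp@density[401],
               tolerance = 1e-10)
  spanned <- flatProfile(2)
  spanned@density[450:800] <- 10
  expect_equal(minmaxRatio(spanned, window = c(2000, 4000),
                           windowBins = 1)$ratio, 5)
  zeroed <- flatProfile(0)
  zeroed@density[500] <- 11
  expect_equal(minmaxRatio(zeroed, window = c(2000, 4000), floor = 0.2,
                           windowBins = 1)$ratio, 55)
})

test_that("the ratio is scale invariant when the floor stays disengaged", {
  set.seed(12)
  p <- DensityProfile(runif(800, 2, 8))
  r1 <- minmaxRatio(p)$ratio
  p3 <- DensityProfile(3 * profileDensity(p))
  expect_equal(minmaxRatio(p3)$ratio, r1, tolerance = 1e-12)
})

test_that("peak search reports the front-relative offset", {
  imp <- flatProfile(0)
  imp@density[321] <- 5   # left edge v = 1600
  pk <- peakStats(imp)
  expect_equal(pk$peak_offset_um, -400)
  expect_false(pk$degenerate)
  flat <- peakStats(flatProfile(2))
  expect_true(flat$degenerate)
  expect_equal(flat$peak_height, 2)
  expect_true(is.na(flat$peak_offset_um))
})

test_that("ties in the peak search break toward the front", {
  p <- flatProfile(0)
  p@density[c(321, 441)] <- 5   # v = 1600 and v = 2200
  expect_equal(peakStats(p)$peak_offset_um, 200)   # 200 < 400 from front
})
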