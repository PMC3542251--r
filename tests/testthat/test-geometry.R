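test_that("front annotation enforces its invariants", {
  expect_error(FrontAnnotation(matrix(c(0, 0), 1, 2), "left"),
               "at least 2 points")
  expect_error(FrontAnnotation(rbind(c(0, 0), c(0, 0)), "left"),
               "distinct")
  expect_s4_class(FrontAnnotation(rbind(c(0, 0), c(10, 0)), "left"),
                  "FrontAnnotation")
})

test_that("ROI placement on an axis-aligned front gives the expected frame", {
  fr <- FrontAnnotation(cbind(c(-3000, 3000), c(0, 0)), tumorSide = "right")
  roi <- buildROI(fr, arcPosition = 3000)
  expect_equal(roi@anchor, c(0, 0))
  expect_equal(roi@normal, c(0, 1))   # tumor below the line (y down)
  # default dimensions: the standard 1 x 4 mm rectangle, 4 mm^2, 5 um bins
  expect_equal(roi@width, 1000)
  expect_equal(roi@length, 4000)
  expect_equal(roi@binWidth, 5)
  expect_equal(roi@width * roi@length / 1e6, 4)   # mm^2
})

test_that("the normal is orthogonal to the local tangent on rotated fronts", {
  for (theta in c(pi / 6, 1.1, -0.4)) {
    pts <- rotate2d(cbind(c(-1000, 1000), c(0, 0)), theta)
    tangent <- (pts[2, ] - pts[1, ]) / sqrt(sum((pts[2, ] - pts[1, ])^2))
    roi <- buildROI(FrontAnnotation(pts, "left"), arcPosition = 500)
    expect_lt(abs(sum(roi@normal * tangent)), 1e-9)
    expect_equal(sqrt(sum(roi@normal^2)), 1, tolerance = 1e-12)
  }
})

test_that("arc positions out of range and degenerate tangents are rejected", {
  fr <- FrontAnnotation(cbind(c(0, 100), c(0, 0)), "left")
  expect_error(buildROI(fr, arcPosition = 101), "out of range")
  expect_error(buildROI(fr, arcPosition = -1), "out of range")
})

test_that("vertex anchors use the angle bisector tangent", {
  # right-angle polyline; at the corner the bisector is at 45 degrees
  fr <- FrontAnnotation(rbind(c(0, 0), c(100, 0), c(100, 100)), "right")
  roi <- buildROI(fr, arcPosition = 100)
  tangent <- c(1, 1) / sqrt(2)
  expect_lt(abs(sum(roi@normal * tangent)), 1e-9)
})

test_that("the front maps to the rectangle midline in (u, v)", {
  roi <- horizontalROI()
  expect_equal(unname(pointToUV(roi@anchor, roi)), c(0, 2000))
  expect_equal(unname(pointToUV(roi@anchor + 500 * roi@normal, roi)),
               c(0, 2500))
  expect_equal(unname(pointToUV(roi@anchor - 2000 * roi@normal, roi)),
               c(0, 0))
})

test_that("uv round-trips through image coordinates", {
  set.seed(42)
  for (rep in 1:5) {
    pts <- rotate2d(cbind(runif(2, -500, 500), c(0, 0)), runif(1, 0, 2 * pi))
    roi <- buildROI(FrontAnnotation(pts, sample(c("left", "right"), 1)),
                    arcPosition = runif(1, 0, 100))
    u <- runif(20, -500, 500); v <- runif(20, 0, 4000)
    uv <- pointToUV(uvToPoint(u, v, roi), roi)
    expect_equal(unname(uv[, "u"]), u, tolerance = 1e-9)
    expect_equal(unname(uv[, "v"]), v, tolerance = 1e-9)
  }
})

test_that("(u, v) coordinates are invariant under joint rotation", {
  set.seed(1)
  base <- cbind(c(-800, 900), c(0, 0))
  pts <- cbind(runif(50, -400, 400), runif(50, -2000, 2000))
  roi0 <- buildROI(FrontAnnotation(base, "right"), arcPosition = 800)
  uv0 <- pointToUV(pts, roi0)
  for (theta in c(0.3, 2.0, -1.2)) {
    roiR <- buildROI(FrontAnnotation(rotate2d(base, theta), "right"),
                     arcPosition = 800)
    uvR <- pointToUV(rotate2d(pts, theta), roiR)
    expect_equal(uvR, uv0, tolerance = 1e-6)
  }
})

test_that("containment respects the rectangle boundary", {
  roi <- horizontalROI()
  tangent <- c(roi@normal[2], -roi@normal[1])
  expect_true(roiContains(roi@anchor, roi))
  expect_false(roiContains(roi@anchor + (roi@width / 2 + 1) * tangent, roi))
  expect_true(roiContains(roi@anchor + (roi@length / 2) * roi@normal, roi))
  expect_false(roiContains(roi@anchor + (roi@length / 2 + 1) * roi@normal,
                           roi))
})

test_that("ROI validity catches bad geometry", {
  expect_error(new("RectangleROI", anchor = c(0, 0), normal = c(0, 2),
                   width = 1000, length = 4000, binWidth = 5),
               "unit vector")
  expect_error(RectangleROI(c(0, 0), c(0, 1), binWidth = 7),
               "divide length")
})
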