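# Fixtures built in code: canonical curves, tiny rendered images, and a
# horizontal-front ROI, shared across test files.

# front along y = 0, tumor below (y > 0 in image coordinates); anchor at
# the middle of the segment
horizontalROI <- function(width = 1000, length = 4000, binWidth = 5) {
  fr <- FrontAnnotation(cbind(c(-3000, 3000), c(0, 0)), tumorSide = "right")
  buildROI(fr, arcPosition = 3000, width = width, length = length,
           binWidth = binWidth)
}

# the three curve archetypes on the standard 800-bin grid
stepProfile <- function(low = 0.5, high = 5)
  DensityProfile(rep(c(low, high), each = 400))

bumpProfile <- function(baseline = 1, height = 6.7, center = 1600,
                        sigma = 150) {
  v <- seq(0, 3995, by = 5)
  DensityProfile(baseline + height * exp(-0.5 * ((v - center) / sigma)^2))
}

flatProfile <- function(level = 0) DensityProfile(rep(level, 800))

# minimal renderer for hand-placed discs: white background, brown cells
discImage <- function(centers, radius = 3.5, nx = 100, ny = 100, mpp = 1,
                      color = c(165, 110, 70), bg = c(255, 255, 255)) {
  px <- array(0, dim = c(nx, ny, 3))
  for (ch in 1:3) px[, , ch] <- bg[ch]
  if (length(centers) > 0) {
    centers <- matrix(centers, ncol = 2)
    for (k in seq_len(nrow(centers))) {
      cx <- centers[k, 1]; cy <- centers[k, 2]
      i <- max(1, ceiling((cx - radius) / mpp)):min(nx, ceiling((cx + radius) / mpp))
      j <- max(1, ceiling((cy - radius) / mpp)):min(ny, ceiling((cy + radius) / mpp))
      hit <- outer(((i - 0.5) * mpp - cx)^2, ((j - 0.5) * mpp - cy)^2,
                   `+`) <= radius^2
      for (ch in 1:3) {
        plane <- px[i, j, ch]
        plane[hit] <- color[ch]
        px[i, j, ch] <- plane
      }
    }
  }
  IHCImage(px, mpp)
}

rotate2d <- function(pts, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  t(R %*% t(pts))
}
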