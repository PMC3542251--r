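# Synthetic infiltration model: expected-density curves for the three
# patterns, Poisson-sampled profiles, rendered slides with ground truth,
# cohorts, and a tissue-microarray core sampling emulator.

#' Expected density along the axis for a simulation config
#'
#' Returns the intensity lambda(v), in cells per 5000 um^2, as a function
#' of the axial position `v` in um (front at `L/2`):
#' pattern 1 is a step from `lambdaOut` to `lambdaIn` at the front;
#' pattern 2 is that baseline step plus an asymmetric Gaussian bump
#' centered `peakMu` um from the front, with outer width `peakSigmaOut`
#' and inner width `peakSigmaIn` (the default -400/200/100 um geometry
#' rises slowly on the host side and falls quickly past the front);
#' pattern 3 is the constant `lambdaOut`.
#'
#' @param cfg a [SimulationConfig-class].
#' @param L axis length in um (default 4000).
#' @return A vectorized function `lambda(v)`.
#' @examples
#' lam <- intensityFunction(SimulationConfig(2))
#' lam(1600)   # baseline + 6.7 at the peak mode, 400 um outside the front
#' @export
intensityFunction <- function(cfg, L = 4000) {
  stopifnot(is(cfg, "SimulationConfig"))
  front <- L / 2
  lo <- cfg@lambdaOut; li <- cfg@lambdaIn
  if (cfg@pattern == 3L) return(function(v) rep(lo, length(v)))
  base <- function(v) ifelse(v < front, lo, li)
  if (cfg@pattern == 1L) return(function(v) base(v))
  ctr <- front + cfg@peakMu
  so <- cfg@peakSigmaOut; si <- cfg@peakSigmaIn; h <- cfg@peakHeight
  function(v) {
    sig <- ifelse(v < ctr, so, si)
    base(v) + h * exp(-0.5 * ((v - ctr) / sig)^2)
  }
}

#' Sample a Poisson density profile from the infiltration model
#'
#' Each 5 um bin covers 5000 um^2 at the reference 1 mm width, so the
#' expected count per bin equals lambda(v) directly and the profile is
#' `density[i] ~ Poisson(lambda(v_i))`, independent across bins, with
#' `v_i` the bin's left edge.
#'
#' @param cfg a [SimulationConfig-class].
#' @param seed integer seed; the draw is reproducible.
#' @param L,binWidth grid, defaults 4000 and 5 um.
#' @return A list with `profile` (a [DensityProfile-class]) and
#'   `true_pattern`.
#' @export
simulateProfile <- function(cfg, seed, L = 4000, binWidth = 5) {
  lam <- intensityFunction(cfg, L = L)
  edges <- seq(0, L, by = binWidth)
  v <- edges[-length(edges)]
  set.seed(seed)
  dens <- rpois(length(v), lam(v))
  list(profile = DensityProfile(density = dens, binEdges = edges,
                                nRectangles = 1, widthUsed = 1000),
       true_pattern = cfg@pattern)
}

#' Draw ground-truth cell positions from the inhomogeneous Poisson model
#'
#' Cell centers over a `width x length` rectangle (local frame: `x` along
#' the axis `v`, `y` across the width) follow an inhomogeneous Poisson
#' process with area rate `lambda(v) / 5000` per um^2, piecewise constant
#' over the 5 um bins. Positions are drawn by inversion: a Poisson total,
#' bin indices proportional to lambda, uniform within bin and across the
#' width.
#'
#' @param cfg a [SimulationConfig-class].
#' @param seed integer seed.
#' @param roiDims named numeric `c(width =, length =)` in um; defaults
#'   1000 x 4000.
#' @param binWidth axial discretization of the intensity, default 5 um.
#' @return An n x 2 matrix of (x, y) positions in um.
#' @export
simulatePoints <- function(cfg, seed, roiDims = c(width = 1000,
                                                  length = 4000),
                           binWidth = 5) {
  W <- roiDims[["width"]]; L <- roiDims[["length"]]
  lam <- intensityFunction(cfg, L = L)
  edges <- seq(0, L, by = binWidth)
  v <- edges[-length(edges)]
  rates <- lam(v) * (W / 1000)       # expected cells per bin at width W
  set.seed(seed)
  n <- rpois(1, sum(rates))
  if (n == 0 || sum(rates) == 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  bin <- sample.int(length(rates), n, replace = TRUE, prob = rates)
  x <- v[bin] + runif(n, 0, binWidth)
  y <- runif(n, 0, W)
  cbind(x = x, y = y)
}

# paint filled discs onto the 3-channel pixel array; `colors` is n x 3
.paintDiscs <- function(px, mpp, centers, radius, colors) {
  d <- dim(px)
  r2 <- radius^2
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    i <- max(1L, ceiling((cx - radius) / mpp)):min(d[1], ceiling((cx + radius) / mpp))
    j <- max(1L, ceiling((cy - radius) / mpp)):min(d[2], ceiling((cy + radius) / mpp))
    if (!length(i) || !length(j)) next
    pcx <- (i - 0.5) * mpp; pcy <- (j - 0.5) * mpp
    hit <- outer((pcx - cx)^2, (pcy - cy)^2, `+`) <= r2
    for (ch in 1:3) {
      plane <- px[i, j, ch]
      plane[hit] <- colors[k, ch]
      px[i, j, ch] <- plane
    }
  }
  px
}

#' Render a synthetic stained slide with ground truth
#'
#' Draws cell positions with [simulatePoints()] and renders them as brown
#' (DAB-like) discs with per-cell color jitter over a pale blue-tinted
#' background scattered with hematoxylin-blue non-positive nuclei, plus
#' mild pixel noise. The rendering is deliberately simple - discs, jitter
#' and noise, not histology texture - but exercises color thresholding,
#' watershed splitting and size filtering exactly as real input would.
#' The invasive front is the vertical line `x = length/2` with tumor at
#' larger `x`, and the returned annotation encodes that orientation.
#'
#' @param cfg a [SimulationConfig-class].
#' @param seed integer seed.
#' @param roiDims `c(width =, length =)` um, defaults 1000 x 4000.
#' @param mpp rendering resolution in um per pixel (default 1).
#' @param nucleusDensity density of blue counterstain-only nuclei per mm^2
#'   (default 400).
#' @return A [SlideTruth-class]: image, true centroids (um), front
#'   annotation, pattern label and config.
#' @export
simulateSlide <- function(cfg, seed, roiDims = c(width = 1000,
                                                 length = 4000),
                          mpp = 1, nucleusDensity = 400) {
  W <- roiDims[["width"]]; L <- roiDims[["length"]]
  cells <- simulatePoints(cfg, seed, roiDims = roiDims)
  # image frame: x = axial position v, y = across-width position u
  nx <- as.integer(ceiling(L / mpp)); ny <- as.integer(ceiling(W / mpp))
  set.seed(seed + 1L)
  px <- array(0, dim = c(nx, ny, 3))
  bg <- c(225, 228, 240)
  for (ch in 1:3) px[, , ch] <- bg[ch]
  nNuc <- rpois(1, nucleusDensity * (W * L / 1e6))
  if (nNuc > 0) {
    nuc <- cbind(runif(nNuc, 0, L), runif(nNuc, 0, W))
    nucCol <- cbind(90 + runif(nNuc, -10, 10), 100 + runif(nNuc, -10, 10),
                    170 + runif(nNuc, 10, 40))
    px <- .paintDiscs(px, mpp, nuc, radius = 3, colors = nucCol)
  }
  if (nrow(cells) > 0) {
    jit <- matrix(runif(3 * nrow(cells), -15, 15), ncol = 3)
    brown <- cbind(165 + jit[, 1], 110 + jit[, 2], 70 + jit[, 3])
    px <- .paintDiscs(px, mpp, cells, radius = cfg@cellRadius,
                      colors = brown)
  }
  px <- px + rnorm(length(px), sd = 6)
  px[px < 0] <- 0; px[px > 255] <- 255
  front <- FrontAnnotation(cbind(c(L / 2, L / 2), c(0, W)),
                           tumorSide = "left")
  new("SlideTruth", image = IHCImage(px, mpp), centroids = cells,
      front = front, truePattern = cfg@pattern, config = cfg)
}

# per-pattern parameter ranges a cohort draw samples from; uniform bounds
.defaultCfgRanges <- function() {
  list(
    `1` = list(lambdaOut = c(0.8, 1.8), lambdaIn = c(3.5, 6.0)),
    `2` = list(lambdaOut = c(0.6, 1.4), lambdaIn = c(1.8, 2.8),
               peakHeight = c(3, 14), peakMu = c(-550, -250),
               peakSigmaOut = c(150, 250), peakSigmaIn = c(70, 130)),
    `3` = list(lambdaOut = c(0.8, 2.6))
  )
}

.drawCfg <- function(pattern, ranges) {
  rng <- ranges[[as.character(pattern)]]
  draw <- function(nm, default) {
    if (!is.null(rng[[nm]])) runif(1, rng[[nm]][1], rng[[nm]][2])
    else default
  }
  lo <- draw("lambdaOut", NULL)
  args <- list(pattern = pattern,
               lambdaOut = lo,
               lambdaIn = if (pattern == 3L) lo else draw("lambdaIn", NULL),
               peakMu = draw("peakMu", -400),
               peakSigmaOut = draw("peakSigmaOut", 200),
               peakSigmaIn = draw("peakSigmaIn", 100),
               peakHeight = draw("peakHeight", 6.7))
  do.call(SimulationConfig, args)
}

#' Simulate a cohort of density profiles with known patterns
#'
#' Draws each patient's true pattern from the mixture (default 21% / 61% /
#' 18%, the prevalences the three archetypes were observed at), then
#' per-patient curve parameters uniformly from `cfgRanges`, then a Poisson
#' profile. Pattern-2 peak heights default to uniform on
#' `[3, 14]` cells per 5000 um^2.
#'
#' @param n number of patients.
#' @param seed integer seed.
#' @param mixture length-3 probabilities summing to 1.
#' @param cfgRanges named list of per-pattern parameter ranges, as in the
#'   default (see source of `lqli:::.defaultCfgRanges`).
#' @return A list with `profiles` (list of [DensityProfile-class]),
#'   `true_pattern` (integer vector) and `configs` (list of
#'   [SimulationConfig-class]).
#' @export
simulateCohort <- function(n, seed, mixture = c(0.21, 0.61, 0.18),
                           cfgRanges = .defaultCfgRanges()) {
  if (abs(sum(mixture) - 1) > 1e-9 || any(mixture < 0))
    stop("mixture must be non-negative and sum to 1")
  if (n == 0)
    return(list(profiles = list(), true_pattern = integer(0),
                configs = list()))
  set.seed(seed)
  labels <- sample.int(3, n, replace = TRUE, prob = mixture)
  configs <- lapply(labels, .drawCfg, ranges = cfgRanges)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  profiles <- vector("list", n)
  for (i in seq_len(n))
    profiles[[i]] <- simulateProfile(configs[[i]], seed = seeds[i])$profile
  list(profiles = profiles, true_pattern = labels, configs = configs)
}

#' Emulate tissue-microarray core sampling of the tumor region
#'
#' Places circular cores (0.6 mm diameter by default) uniformly at random
#' within the tumor region of a ground-truth point field, counts the cells
#' falling in each, and reports the mean density per mm^2 over the cores -
#' the quantity a TMA-based study measures. Comparing its seed-to-seed
#' variability with whole-rectangle totals quantifies how much the small
#' core area inflates count variability.
#'
#' @param truth a [SlideTruth-class], or a plain n x 2 centroid matrix.
#' @param region for a centroid matrix, the sampling region as
#'   `c(x_lo, x_hi, y_lo, y_hi)` in um; for a [SlideTruth-class] it
#'   defaults to the tumor half of the slide.
#' @param coreDiameter core diameter in um (default 600).
#' @param nCores number of cores (default 3).
#' @param seed integer seed for core placement.
#' @return A list with `mean_density_mm2`, `per_core_density_mm2`,
#'   `per_core_count`, `centers`.
#' @export
simulateTMADensity <- function(truth, region = NULL, coreDiameter = 600,
                               nCores = 3, seed = 1) {
  if (is(truth, "SlideTruth")) {
    cc <- truth@centroids
    d <- dim(truth@image@pixels)
    L <- d[1] * truth@image@mpp; W <- d[2] * truth@image@mpp
    if (is.null(region)) region <- c(L / 2, L, 0, W)
  } else {
    cc <- as.matrix(truth)
    if (is.null(region)) stop("region is required for a centroid matrix")
  }
  r <- coreDiameter / 2
  if (region[2] - region[1] < coreDiameter ||
      region[4] - region[3] < coreDiameter)
    stop("region too small to hold a core")
  set.seed(seed)
  ctr <- cbind(runif(nCores, region[1] + r, region[2] - r),
               runif(nCores, region[3] + r, region[4] - r))
  areaMM2 <- pi * r^2 / 1e6
  counts <- vapply(seq_len(nCores), function(k) {
    if (nrow(cc) == 0) return(0L)
    sum((cc[, 1] - ctr[k, 1])^2 + (cc[, 2] - ctr[k, 2])^2 <= r^2)
  }, integer(1))
  dens <- counts / areaMM2
  list(mean_density_mm2 = mean(dens), per_core_density_mm2 = dens,
       per_core_count = counts, centers = ctr)
}

#' Match detections to ground-truth centroids
#'
#' Greedy nearest-pair matching within a radius: the closest
#' detection-truth pair is matched first, both are removed, and so on.
#' Standard recall/precision bookkeeping for detector validation.
#'
#' @param detected n x 2 matrix or data.frame with `x_um`, `y_um` columns.
#' @param truth m x 2 matrix of true centers (um).
#' @param radius maximum match distance in um (default 4).
#' @return A list with `n_matched`, `recall`, `precision`.
#' @export
matchCentroids <- function(detected, truth, radius = 4) {
  if (is.data.frame(detected)) detected <- cbind(detected$x_um, detected$y_um)
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(n_matched = 0L, recall = ifelse(nt == 0, NA, 0),
                precision = ifelse(nd == 0, NA, 0)))
  dx <- outer(detected[, 1], truth[, 1], `-`)
  dy <- outer(detected[, 2], truth[, 2], `-`)
  dist2 <- dx^2 + dy^2
  cand <- which(dist2 <= radius^2)
  # greedy closest-pair-first: equivalent to repeatedly extracting the
  # global minimum, but one stable sort over the candidate pairs
  cand <- cand[order(dist2[cand])]
  di <- (cand - 1L) %% nd + 1L
  tj <- (cand - 1L) %/% nd + 1L
  dFree <- rep(TRUE, nd); tFree <- rep(TRUE, nt)
  matched <- 0L
  for (k in seq_along(cand)) {
    if (dFree[di[k]] && tFree[tj[k]]) {
      dFree[di[k]] <- FALSE
      tFree[tj[k]] <- FALSE
      matched <- matched + 1L
    }
  }
  list(n_matched = matched, recall = matched / nt,
       precision = matched / nd)
}
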