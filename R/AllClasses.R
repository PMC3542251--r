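#' @import methods
#' @importFrom stats rpois runif rnorm
#' @importFrom utils read.csv write.csv packageVersion
#' @importFrom tools md5sum
NULL

#' FrontAnnotation: an annotated tumor invasive front
#'
#' An oriented polyline tracing the microscopic interface between host
#' tissue and tumor mass, together with a flag saying on which side of the
#' travel direction the tumor lies. All coordinates are in micrometers, in
#' the image frame (origin top-left, y pointing down).
#'
#' @slot points numeric matrix with two columns (x, y in um), one row per
#'   vertex, at least two rows, consecutive vertices distinct.
#' @slot tumorSide character, `"left"` or `"right"`: the side of the
#'   oriented polyline (relative to the direction of travel) that contains
#'   tumor tissue.
#'
#' @seealso [FrontAnnotation()], [buildROI()]
#' @export
setClass("FrontAnnotation",
  representation(points = "matrix", tumorSide = "character"))

setValidity("FrontAnnotation", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L)
    return("points must be a numeric matrix with 2 columns (x, y in um)")
  if (nrow(p) < 2L)
    return("a front needs at least 2 points")
  if (any(!is.finite(p)))
    return("front coordinates must be finite")
  seg <- diff(p)
  if (any(sqrt(rowSums(seg^2)) == 0))
    return("consecutive front points must be distinct")
  if (length(object@tumorSide) != 1L ||
      !object@tumorSide %in% c("left", "right"))
    return("tumorSide must be \"left\" or \"right\"")
  TRUE
})

#' Construct a FrontAnnotation
#'
#' @param points numeric matrix (n x 2) of vertex coordinates in um.
#' @param tumorSide `"left"` or `"right"` of the travel direction. In image
#'   coordinates (y down), walking along the polyline, "right" is the side
#'   reached by rotating the travel direction a quarter turn clockwise on
#'   screen.
#' @return A [FrontAnnotation-class] object.
#' @examples
#' fr <- FrontAnnotation(cbind(c(0, 1000), c(0, 0)), tumorSide = "right")
#' @export
FrontAnnotation <- function(points, tumorSide = c("left", "right")) {
  tumorSide <- match.arg(tumorSide)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  new("FrontAnnotation", points = points, tumorSide = tumorSide)
}

#' RectangleROI: the analysis rectangle over the invasive front
#'
#' The 1 mm x 4 mm analysis rectangle. Its local frame has a coordinate
#' `u` running across the width (along the front) and `v` running along the
#' 4 mm axis, from host tissue (v = 0) across the front (v = L/2) into the
#' tumor (v = L).
#'
#' @slot anchor numeric length-2: a point on the front, um (image frame).
#' @slot normal numeric length-2 unit vector perpendicular to the front at
#'   the anchor, pointing into the tumor.
#' @slot width width W of the rectangle in um (default 1000).
#' @slot length length L of the rectangle in um (default 4000).
#' @slot binWidth axial bin size in um (default 5); must divide L exactly.
#'
#' @seealso [RectangleROI()], [buildROI()], [pointToUV()]
#' @export
setClass("RectangleROI",
  representation(anchor = "numeric", normal = "numeric",
                 width = "numeric", length = "numeric",
                 binWidth = "numeric"))

setValidity("RectangleROI", function(object) {
  if (length(object@anchor) != 2L || any(!is.finite(object@anchor)))
    return("anchor must be a finite length-2 numeric")
  n <- object@normal
  if (length(n) != 2L || abs(sqrt(sum(n^2)) - 1) > 1e-9)
    return("normal must be a unit vector (|normal| = 1 within 1e-9)")
  if (object@width <= 0) return("width must be > 0")
  if (object@length <= 0) return("length must be > 0")
  if (object@binWidth <= 0) return("binWidth must be > 0")
  nbin <- object@length / object@binWidth
  if (abs(nbin - round(nbin)) > 1e-9)
    return("binWidth must divide length exactly")
  TRUE
})

#' Construct a RectangleROI directly
#'
#' Most users will call [buildROI()] on a [FrontAnnotation-class] instead.
#'
#' @param anchor point on the front (um).
#' @param normal unit vector pointing into the tumor.
#' @param width,length rectangle dimensions in um; defaults 1000 x 4000.
#' @param binWidth axial bin size in um, default 5.
#' @return A [RectangleROI-class] object covering `width * length` um^2.
#' @export
RectangleROI <- function(anchor, normal, width = 1000, length = 4000,
                         binWidth = 5) {
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) stop("normal must be non-zero")
  new("RectangleROI", anchor = as.numeric(anchor),
      normal = as.numeric(normal) / nrm,
      width = as.numeric(width), length = as.numeric(length),
      binWidth = as.numeric(binWidth))
}

#' IHCImage: an RGB immunohistochemistry raster with physical calibration
#'
#' @slot pixels numeric array `c(nx, ny, 3)` of RGB values on the 0-255
#'   scale; `x` runs along the first dimension, `y` (down) along the
#'   second, matching image coordinates so that pixel `(i, j)` is centered
#'   at `((i - 0.5) * mpp, (j - 0.5) * mpp)` um.
#' @slot mpp microns per pixel (isotropic), > 0.
#' @export
setClass("IHCImage", representation(pixels = "array", mpp = "numeric"))

setValidity("IHCImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an nx x ny x 3 RGB array")
  if (length(object@mpp) != 1L || !is.finite(object@mpp) || object@mpp <= 0)
    return("mpp must be a single positive number")
  TRUE
})

#' Construct an IHCImage
#'
#' @param pixels numeric array `c(nx, ny, 3)`, RGB in 0-255.
#' @param mpp microns per pixel.
#' @return An [IHCImage-class].
#' @export
IHCImage <- function(pixels, mpp) {
  new("IHCImage", pixels = pixels, mpp = as.numeric(mpp))
}

#' DetectionParams: tunables of the three-step lymphocyte detector
#'
#' The three parameters exposed to the user are the ones that matter in
#' practice: object size bounds and the blue/red intensity thresholds of
#' the color rule. A pixel is candidate-positive (DAB brown) when its blue
#' value is below `blueIntensity`, its red value is above `redIntensity`,
#' and red exceeds blue.
#'
#' @slot sizeMin,sizeMax object area bounds in um^2 (defaults 15 and 150,
#'   lymphocyte scale: equivalent diameters ~4.4-13.8 um).
#' @slot blueIntensity counterstain rejection threshold on 0-255
#'   (default 160).
#' @slot redIntensity positive-stain threshold on 0-255 (default 100).
#' @export
setClass("DetectionParams",
  representation(sizeMin = "numeric", sizeMax = "numeric",
                 blueIntensity = "numeric", redIntensity = "numeric"))

setValidity("DetectionParams", function(object) {
  if (!(object@sizeMin > 0 && object@sizeMin < object@sizeMax))
    return("need 0 < sizeMin < sizeMax")
  th <- c(object@blueIntensity, object@redIntensity)
  if (any(th < 0 | th > 255))
    return("intensity thresholds must lie in [0, 255]")
  TRUE
})

#' Construct DetectionParams
#'
#' @param sizeMin,sizeMax area bounds in um^2.
#' @param blueIntensity,redIntensity color thresholds on 0-255.
#' @return A [DetectionParams-class].
#' @examples
#' DetectionParams()                   # defaults
#' DetectionParams(sizeMin = 20)      # override one tunable
#' @export
DetectionParams <- function(sizeMin = 15, sizeMax = 150,
                            blueIntensity = 160, redIntensity = 100) {
  new("DetectionParams", sizeMin = sizeMin, sizeMax = sizeMax,
      blueIntensity = blueIntensity, redIntensity = redIntensity)
}

#' DensityProfile: lymphocyte density versus distance from the front
#'
#' Densities are cells per 5000 um^2 per 5 um axial segment, standardized
#' to a 1 mm analysis width, reported on bins spanning `[0, L]` with the
#' invasive front at `L/2`. Bin `i` covers `[edges[i], edges[i+1])`
#' (half-open; the last bin is closed) and is addressed by its left edge.
#'
#' @slot binEdges numeric vector of bin edges in um, `length(density) + 1`
#'   values, strictly increasing, evenly spaced.
#' @slot density numeric vector, cells per 5000 um^2 per bin, all >= 0.
#' @slot nRectangles number of analysis rectangles merged into this curve.
#' @slot widthUsed analysis width W in um the counts were taken over.
#' @export
setClass("DensityProfile",
  representation(binEdges = "numeric", density = "numeric",
                 nRectangles = "numeric", widthUsed = "numeric"))

setValidity("DensityProfile", function(object) {
  e <- object@binEdges
  if (length(e) != length(object@density) + 1L)
    return("need length(binEdges) == length(density) + 1")
  if (any(diff(e) <= 0)) return("bin edges must be strictly increasing")
  if (any(object@density < 0)) return("densities must be >= 0")
  if (object@widthUsed <= 0) return("widthUsed must be > 0")
  TRUE
})

#' Construct a DensityProfile
#'
#' @param density cells per 5000 um^2 per bin.
#' @param binEdges bin edges in um; default the standard grid
#'   `seq(0, 4000, by = 5)` when `density` has 800 values.
#' @param nRectangles how many rectangles were merged (default 1).
#' @param widthUsed analysis width in um (default 1000).
#' @return A [DensityProfile-class].
#' @export
DensityProfile <- function(density,
                           binEdges = seq(0, length(density) * 5, by = 5),
                           nRectangles = 1, widthUsed = 1000) {
  new("DensityProfile", binEdges = as.numeric(binEdges),
      density = as.numeric(density), nRectangles = as.numeric(nRectangles),
      widthUsed = as.numeric(widthUsed))
}

#' ClassifierConfig: thresholds of the pattern-classification cascade
#'
#' @slot tauLow density threshold (cells per 5000 um^2) under which a curve
#'   counts as "low" (default 3, the smallest peri-marginal peak treated as
#'   significant).
#' @slot rhoIn intratumoral dominance ratio for pattern 1 (default 1.5).
#' @slot piPeak peak prominence ratio over the flank baseline for pattern 2
#'   (default 2).
#' @slot windowBins smoothing window in bins applied before classification
#'   (odd, default 21 = 105 um).
#' @slot tumorCore,peritumoral,margin numeric length-2 windows in um over
#'   which the intratumoral mean, the peritumoral mean and the marginal
#'   peak are measured; defaults `[2500, 4000]`, `[0, 1500]`,
#'   `[1400, 2400]`.
#' @export
setClass("ClassifierConfig",
  representation(tauLow = "numeric", rhoIn = "numeric", piPeak = "numeric",
                 windowBins = "numeric", tumorCore = "numeric",
                 peritumoral = "numeric", margin = "numeric"))

setValidity("ClassifierConfig", function(object) {
  if (object@tauLow <= 0) return("tauLow must be > 0")
  if (object@rhoIn <= 1) return("rhoIn must be > 1")
  if (object@piPeak <= 1) return("piPeak must be > 1")
  w <- object@windowBins
  if (w < 1 || w %% 2 != 1) return("windowBins must be odd and >= 1")
  for (nm in c("tumorCore", "peritumoral", "margin")) {
    win <- slot(object, nm)
    if (length(win) != 2L || win[1] >= win[2])
      return(sprintf("%s must be an increasing length-2 window", nm))
  }
  TRUE
})

#' Construct a ClassifierConfig
#'
#' @param tauLow,rhoIn,piPeak cascade thresholds; see
#'   [ClassifierConfig-class].
#' @param windowBins smoothing window (odd number of 5 um bins).
#' @param tumorCore,peritumoral,margin measurement windows in um.
#' @return A [ClassifierConfig-class].
#' @export
ClassifierConfig <- function(tauLow = 3, rhoIn = 1.5, piPeak = 2,
                             windowBins = 21,
                             tumorCore = c(2500, 4000),
                             peritumoral = c(0, 1500),
                             margin = c(1400, 2400)) {
  new("ClassifierConfig", tauLow = tauLow, rhoIn = rhoIn, piPeak = piPeak,
      windowBins = windowBins, tumorCore = tumorCore,
      peritumoral = peritumoral, margin = margin)
}

#' PatternCall: the classification of one density curve
#'
#' @slot pattern integer 1, 2 or 3: high intratumoral density, peak near
#'   the invasive margin, or uniform low density.
#' @slot peakOffset position of the marginal density maximum in um relative
#'   to the front (negative = outside the tumor).
#' @slot peakHeight smoothed density at the peak, cells per 5000 um^2.
#' @slot mIn,mOut mean smoothed densities over the tumor-core and
#'   peritumoral windows.
#' @slot ruleFired which cascade rule produced the call ("R1", "R2", "R3").
#' @slot degenerate TRUE when the curve was flat over the margin window so
#'   the peak location is arbitrary.
#' @export
setClass("PatternCall",
  representation(pattern = "integer", peakOffset = "numeric",
                 peakHeight = "numeric", mIn = "numeric", mOut = "numeric",
                 ruleFired = "character", degenerate = "logical"))

setValidity("PatternCall", function(object) {
  if (!object@pattern %in% 1:3) return("pattern must be 1, 2 or 3")
  if (object@mIn < 0 || object@mOut < 0)
    return("window means must be >= 0")
  TRUE
})

#' SimulationConfig: parameters of the synthetic infiltration model
#'
#' Encodes the expected lymphocyte density lambda(v) (cells per 5000 um^2)
#' along the 4 mm axis for the three infiltration patterns: a step at the
#' front (pattern 1), a baseline step plus an asymmetric Gaussian peak just
#' outside the front (pattern 2), or a uniform low density (pattern 3).
#' The peak defaults place its mode 400 um outside the front with a slow
#' 200 um rise on the host side and a fast 100 um decline into the tumor,
#' at a height of 6.7 cells per 5000 um^2.
#'
#' @slot pattern integer 1, 2 or 3.
#' @slot lambdaOut,lambdaIn baseline densities outside/inside the tumor,
#'   cells per 5000 um^2.
#' @slot peakMu peak center offset from the front in um (negative =
#'   outside; default -400).
#' @slot peakSigmaOut,peakSigmaIn outer/inner peak widths in um (defaults
#'   200 and 100).
#' @slot peakHeight peak height above baseline, cells per 5000 um^2
#'   (default 6.7).
#' @slot cellRadius rendered cell radius in um (default 3.5).
#' @export
setClass("SimulationConfig",
  representation(pattern = "integer", lambdaOut = "numeric",
                 lambdaIn = "numeric", peakMu = "numeric",
                 peakSigmaOut = "numeric", peakSigmaIn = "numeric",
                 peakHeight = "numeric", cellRadius = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (!object@pattern %in% 1:3) return("pattern must be 1, 2 or 3")
  if (object@lambdaOut < 0 || object@lambdaIn < 0 || object@peakHeight < 0)
    return("densities must be >= 0")
  if (object@peakSigmaOut <= 0 || object@peakSigmaIn <= 0)
    return("peak widths must be > 0")
  if (object@cellRadius <= 0) return("cellRadius must be > 0")
  TRUE
})

#' Construct a SimulationConfig
#'
#' Pattern-specific baseline defaults are calibrated to tissue-microarray
#' densities of 922, 581 and 392 cells/mm^2 for patterns 1, 2 and 3
#' (4.61, 2.91 and 1.96 cells per 5000 um^2 after the x 0.005 unit
#' conversion): the pattern-1 intratumoral baseline is 4.61 and the
#' pattern-3 uniform density 1.96. The pattern-2 intratumoral baseline is
#' set slightly lower, at 2.5, so that a pattern-2 tumor core stays
#' clearly below the 3.0 cells per 5000 um^2 "low" threshold that
#' separates it from pattern 1; see the methods vignette for this
#' calibration choice.
#'
#' @param pattern 1, 2 or 3.
#' @param lambdaOut,lambdaIn baselines, cells per 5000 um^2; pattern-aware
#'   defaults when NULL.
#' @param peakMu,peakSigmaOut,peakSigmaIn,peakHeight pattern-2 peak shape.
#' @param cellRadius rendered cell radius in um.
#' @return A [SimulationConfig-class].
#' @examples
#' SimulationConfig(2)   # the peri-marginal peak archetype
#' @export
SimulationConfig <- function(pattern, lambdaOut = NULL, lambdaIn = NULL,
                             peakMu = -400, peakSigmaOut = 200,
                             peakSigmaIn = 100, peakHeight = 6.7,
                             cellRadius = 3.5) {
  pattern <- as.integer(pattern)
  if (is.null(lambdaOut))
    lambdaOut <- switch(pattern, `1` = 1.5, `2` = 1.0, `3` = 1.96)
  if (is.null(lambdaIn))
    lambdaIn <- switch(pattern, `1` = 4.61, `2` = 2.5, `3` = 1.96)
  new("SimulationConfig", pattern = pattern,
      lambdaOut = as.numeric(lambdaOut), lambdaIn = as.numeric(lambdaIn),
      peakMu = peakMu, peakSigmaOut = peakSigmaOut,
      peakSigmaIn = peakSigmaIn, peakHeight = peakHeight,
      cellRadius = cellRadius)
}

#' SlideTruth: a rendered synthetic slide with its ground truth
#'
#' @slot image the rendered [IHCImage-class].
#' @slot centroids matrix (n x 2) of true cell centers in um.
#' @slot front the [FrontAnnotation-class] of the synthetic invasive front.
#' @slot truePattern integer 1-3, the pattern the slide was drawn from.
#' @slot config the [SimulationConfig-class] used.
#' @export
setClass("SlideTruth",
  representation(image = "IHCImage", centroids = "matrix",
                 front = "FrontAnnotation", truePattern = "integer",
                 config = "SimulationConfig"))

setValidity("SlideTruth", function(object) {
  cc <- object@centroids
  if (nrow(cc) > 0) {
    d <- dim(object@image@pixels)
    lim <- c(d[1], d[2]) * object@image@mpp
    if (any(cc[, 1] < 0 | cc[, 1] > lim[1] | cc[, 2] < 0 | cc[, 2] > lim[2]))
      return("all centroids must lie inside the image")
  }
  TRUE
})

setMethod("show", "FrontAnnotation", function(object) {
  seg <- diff(object@points)
  cat(sprintf("FrontAnnotation: %d points, arc length %.1f um, tumor on the %s\n",
              nrow(object@points), sum(sqrt(rowSums(seg^2))),
              object@tumorSide))
})

setMethod("show", "RectangleROI", function(object) {
  cat(sprintf(
    "RectangleROI: %g x %g um (%.2f mm^2), bin %g um, anchor (%.1f, %.1f), normal (%.3f, %.3f)\n",
    object@width, object@length, object@width * object@length / 1e6,
    object@binWidth, object@anchor[1], object@anchor[2],
    object@normal[1], object@normal[2]))
})

setMethod("show", "IHCImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("IHCImage: %d x %d px at %.3g um/px (%.2f x %.2f mm)\n",
              d[1], d[2], object@mpp, d[1] * object@mpp / 1000,
              d[2] * object@mpp / 1000))
})

setMethod("show", "DensityProfile", function(object) {
  cat(sprintf(
    "DensityProfile: %d bins of %g um over [%g, %g] um, %g rectangle(s), width %g um\n",
    length(object@density), diff(object@binEdges[1:2]),
    min(object@binEdges), max(object@binEdges), object@nRectangles,
    object@widthUsed))
  cat(sprintf("  density (cells/5000 um^2): mean %.2f, max %.2f\n",
              mean(object@density), max(object@density)))
})

setMethod("show", "PatternCall", function(object) {
  cat(sprintf(
    "PatternCall: pattern %d (%s)\n  peak %.2f cells/5000 um^2 at %+.0f um from front; m_in %.2f, m_out %.2f%s\n",
    object@pattern, object@ruleFired, object@peakHeight,
    object@peakOffset, object@mIn, object@mOut,
    if (object@degenerate) " [degenerate: flat curve]" else ""))
})

setMethod("show", "SlideTruth", function(object) {
  cat(sprintf("SlideTruth: pattern %d, %d true cells\n",
              object@truePattern, nrow(object@centroids)))
  show(object@image)
})

# ---- accessors ----

#' Accessors for the core classes
#'
#' Small getters so downstream code never reaches into slots:
#' `profileDensity()` and `profileBinEdges()` read a
#' [DensityProfile-class]; `patternOf()` reads the integer pattern from a
#' [PatternCall-class]; `truthCentroids()` and `truthImage()` read a
#' [SlideTruth-class].
#'
#' @param x the object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
profileDensity <- function(x) x@density

#' @rdname accessors
#' @export
profileBinEdges <- function(x) x@binEdges

#' @rdname accessors
#' @export
patternOf <- function(x) x@pattern

#' @rdname accessors
#' @export
truthCentroids <- function(x) x@centroids

#' @rdname accessors
#' @export
truthImage <- function(x) x@image
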