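# From detections to density-vs-distance curves: 5 um binning,
# standardization to cells per 5000 um^2, merging, smoothing, and
# heterogeneity statistics.

.binLeft <- function(p) p@binEdges[-length(p@binEdges)]

# indices of bins whose segment [v, v + delta) lies inside [lo, hi]
.binsInWindow <- function(p, window) {
  v <- .binLeft(p)
  which(v >= window[1] - 1e-9 & v <= window[2] - diff(p@binEdges[1:2]) + 1e-9)
}

#' Count detections in 5 um segments along the rectangle axis
#'
#' Assigns each detection inside the rectangle to the axial segment
#' containing its `v` coordinate. Segments are half-open `[v, v + delta)`
#' except the last, which is closed so a cell exactly on the inner edge is
#' still counted. The counts sum to the number of detections inside the
#' ROI.
#'
#' @param dets data.frame of detections with `x_um`, `y_um` columns (as
#'   from [detectCells()]).
#' @param roi the [RectangleROI-class] the detections belong to.
#' @return Integer vector of length `L / binWidth` (800 at defaults).
#' @export
binCounts <- function(dets, roi) {
  stopifnot(is(roi, "RectangleROI"))
  nbin <- as.integer(round(roi@length / roi@binWidth))
  if (nrow(dets) == 0) return(integer(nbin))
  pts <- cbind(dets$x_um, dets$y_um)
  uv <- pointToUV(pts, roi)
  inside <- abs(uv[, "u"]) <= roi@width / 2 & uv[, "v"] >= 0 &
    uv[, "v"] <= roi@length
  v <- uv[inside, "v"]
  idx <- pmin(floor(v / roi@binWidth) + 1L, nbin)  # v = L joins the last bin
  tabulate(idx, nbins = nbin)
}

#' Standardize segment counts to cells per 5000 um^2
#'
#' Counts taken over a rectangle of width `W` are scaled to the reference
#' 1 mm width, so each density value corresponds to a
#' `binWidth x 1000 um = 5000 um^2` segment area at the default 5 um bin:
#' `density = count * 1000 / W`. At `W = 1000` um the density equals the
#' raw count.
#'
#' @param counts integer vector from [binCounts()].
#' @param roi the [RectangleROI-class] the counts were taken over.
#' @return A [DensityProfile-class] with `nRectangles = 1`.
#' @export
toDensity <- function(counts, roi) {
  stopifnot(is(roi, "RectangleROI"))
  if (roi@width <= 0) stop("roi width must be > 0")
  DensityProfile(density = counts * (1000 / roi@width),
                 binEdges = seq(0, roi@length, by = roi@binWidth),
                 nRectangles = 1, widthUsed = roi@width)
}

#' Merge density curves from several rectangles into a mean curve
#'
#' Per-bin arithmetic mean of the input curves, which must share the same
#' bin grid. The merged curve records how many rectangles contributed.
#'
#' @param profiles list of [DensityProfile-class] objects on one grid.
#' @return A [DensityProfile-class]; the mean curve.
#' @export
mergeProfiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  e <- profiles[[1]]@binEdges
  for (p in profiles)
    if (length(p@binEdges) != length(e) || any(abs(p@binEdges - e) > 1e-9))
      stop("profiles must share the same bin grid")
  dens <- rowMeans(vapply(profiles, profileDensity,
                          numeric(length(e) - 1L)))
  DensityProfile(density = dens, binEdges = e,
                 nRectangles = length(profiles),
                 widthUsed = mean(vapply(profiles, function(p) p@widthUsed,
                                         numeric(1))))
}

#' Smooth a density curve with a centered moving average
#'
#' Windows are truncated at the curve ends (shorter one-sided windows), so
#' no bins are lost and a constant curve is unchanged. `windowBins = 1` is
#' the identity.
#'
#' @param p a [DensityProfile-class].
#' @param windowBins odd window size in bins (default 21, i.e. 105 um at
#'   5 um bins: below the 200-400 um structure scale of the curves, above
#'   per-bin Poisson noise).
#' @return The smoothed [DensityProfile-class].
#' @export
smoothProfile <- function(p, windowBins = 21) {
  stopifnot(is(p, "DensityProfile"))
  if (windowBins < 1 || windowBins %% 2 != 1)
    stop("windowBins must be odd and >= 1")
  if (windowBins == 1) return(p)
  x <- p@density
  n <- length(x)
  h <- (windowBins - 1L) / 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  DensityProfile(density = sm, binEdges = p@binEdges,
                 nRectangles = p@nRectangles, widthUsed = p@widthUsed)
}

#' Max/min density ratio over a window: infiltration heterogeneity
#'
#' Measures how variable the infiltrate is over part of the curve as
#' `max(s) / max(min(s), floor)` on the smoothed curve `s`. The floor is a
#' pseudo-density that caps the ratio when bins are empty; curves are
#' smoothed first because single 5 um segments are Poisson-noisy.
#'
#' @param p a [DensityProfile-class].
#' @param window length-2 numeric `[v_lo, v_hi]` um; default the tumor
#'   region `[2000, 4000]`.
#' @param floor pseudo-density floor (default 0.2 cells per 5000 um^2).
#' @param windowBins smoothing window applied before taking max/min
#'   (default 21; pass 1 for a pre-smoothed curve).
#' @return A list with `ratio`, `window`, `floor_used`, and the `max` and
#'   `min` smoothed densities found.
#' @export
minmaxRatio <- function(p, window = c(2000, 4000), floor = 0.2,
                        windowBins = 21) {
  stopifnot(is(p, "DensityProfile"), length(window) == 2L,
            window[1] < window[2])
  s <- smoothProfile(p, windowBins)
  idx <- .binsInWindow(s, window)
  if (length(idx) == 0) stop("window contains no bins")
  sv <- s@density[idx]
  list(ratio = max(sv) / max(min(sv), floor),
       window = window, floor_used = floor,
       max = max(sv), min = min(sv))
}

#' Locate the density peak near the invasive margin
#'
#' Finds the maximum of a smoothed curve over the margin window and
#' reports it as an offset from the front (negative = outside the tumor).
#' Ties are broken toward the front. A curve that is flat over the window
#' is flagged degenerate: its "peak" location is arbitrary and the offset
#' is reported as NA.
#'
#' @param p a smoothed [DensityProfile-class] (smooth with
#'   [smoothProfile()] first; this function does not smooth).
#' @param margin length-2 search window in um, default `[1400, 2400]`
#'   (600 um outside to 400 um inside the front).
#' @return A list with `peak_offset_um`, `peak_height`, `degenerate`.
#' @export
peakStats <- function(p, margin = c(1400, 2400)) {
  stopifnot(is(p, "DensityProfile"))
  front <- (min(p@binEdges) + max(p@binEdges)) / 2
  idx <- .binsInWindow(p, margin)
  if (length(idx) == 0) stop("margin window contains no bins")
  v <- .binLeft(p)[idx]
  s <- p@density[idx]
  if (diff(range(s)) == 0) {
    return(list(peak_offset_um = NA_real_, peak_height = s[1],
                degenerate = TRUE))
  }
  at <- which(s == max(s))
  at <- at[order(abs(v[at] - front), v[at])][1]  # ties: toward the front
  list(peak_offset_um = v[at] - front, peak_height = s[at],
       degenerate = FALSE)
}
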