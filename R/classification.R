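# Pattern classification of mean density curves: an explicit rule cascade
# standing in for the visual calls of trained observers.

.meanOver <- function(p, window) {
  idx <- .binsInWindow(p, window)
  mean(p@density[idx])
}

#' Classify a density curve into infiltration pattern 1, 2 or 3
#'
#' Applies a deterministic cascade to the smoothed curve `s`:
#' \describe{
#'   \item{R1 (pattern 1, high intratumoral density)}{the tumor-core mean
#'     `m_in` reaches `tauLow` and dominates both the peritumoral mean and
#'     the outer-flank baseline by at least `rhoIn`.}
#'   \item{R2 (pattern 2, peri-marginal peak)}{otherwise, the maximum of
#'     `s` over the margin window reaches `tauLow` and stands at least
#'     `piPeak` times above the baseline (mean of `s` outside the margin
#'     window).}
#'   \item{R3 (pattern 3, uniform low density)}{otherwise.}
#' }
#' Pattern 1 takes precedence over pattern 2, resolving curves that are
#' both high inside and peaked at the margin. The outer-flank baseline
#' used by R1 is the mean of `s` outside the margin window on the host
#' side only, so that a strong intratumoral plateau is not compared
#' against itself.
#'
#' @param p a [DensityProfile-class] on the standard `[0, L]` grid (raw;
#'   smoothing is applied internally with `cfg@windowBins`).
#' @param cfg a [ClassifierConfig-class].
#' @return A [PatternCall-class].
#' @examples
#' step <- DensityProfile(rep(c(0.5, 5), each = 400))
#' patternOf(classifyProfile(step))   # 1
#' @export
classifyProfile <- function(p, cfg = ClassifierConfig()) {
  stopifnot(is(p, "DensityProfile"), is(cfg, "ClassifierConfig"))
  L <- max(p@binEdges) - min(p@binEdges)
  s <- smoothProfile(p, cfg@windowBins)
  mIn <- .meanOver(s, cfg@tumorCore)
  mOut <- .meanOver(s, cfg@peritumoral)
  pk <- peakStats(s, margin = cfg@margin)
  outerFlank <- if (cfg@margin[1] > min(p@binEdges))
    .meanOver(s, c(min(p@binEdges), cfg@margin[1])) else 0
  inMargin <- .binsInWindow(s, cfg@margin)
  baseline <- mean(s@density[-inMargin])
  if (mIn >= cfg@tauLow && mIn >= cfg@rhoIn * max(mOut, outerFlank)) {
    pattern <- 1L; rule <- "R1"
  } else if (!pk$degenerate && pk$peak_height >= cfg@tauLow &&
             pk$peak_height >= cfg@piPeak * baseline) {
    pattern <- 2L; rule <- "R2"
  } else {
    pattern <- 3L; rule <- "R3"
  }
  new("PatternCall", pattern = pattern,
      peakOffset = pk$peak_offset_um, peakHeight = pk$peak_height,
      mIn = mIn, mOut = mOut, ruleFired = rule,
      degenerate = pk$degenerate)
}

#' Classify a list of density curves
#'
#' Element-wise [classifyProfile()], order preserved.
#'
#' @param profiles non-empty list of [DensityProfile-class] objects.
#' @param cfg a [ClassifierConfig-class].
#' @return A list of [PatternCall-class] objects.
#' @export
classifyCohort <- function(profiles, cfg = ClassifierConfig()) {
  if (length(profiles) == 0) stop("empty profile list")
  lapply(profiles, classifyProfile, cfg = cfg)
}
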