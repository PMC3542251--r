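# Cohort-level summaries: pattern frequencies, dual-marker concordance,
# and chance-corrected interobserver agreement.

#' Pattern frequencies in a cohort
#'
#' Counts and integer percentages of patterns 1-3. Percentages are rounded
#' to the nearest integer, half away from zero, and may sum to 100 plus or
#' minus 1.
#'
#' @param calls integer vector of patterns in `{1, 2, 3}` (or a list of
#'   [PatternCall-class] objects).
#' @return A data.frame with columns `pattern`, `count`, `percent`.
#' @examples
#' patternFrequencies(c(rep(1, 24), rep(2, 71), rep(3, 22)))
#' @export
patternFrequencies <- function(calls) {
  calls <- .asPatterns(calls)
  if (length(calls) == 0) stop("empty input")
  n <- length(calls)
  counts <- vapply(1:3, function(k) sum(calls == k), integer(1))
  data.frame(pattern = 1:3, count = counts,
             percent = floor(100 * counts / n + 0.5))
}

.asPatterns <- function(x) {
  if (is.list(x)) x <- vapply(x, patternOf, integer(1))
  x <- as.integer(x)
  if (any(!x %in% 1:3)) stop("patterns must be 1, 2 or 3")
  x
}

#' Concordance between two markers' pattern calls
#'
#' How often the same tumor receives the same pattern with two antibodies,
#' plus the cross-table of discordant pairs.
#'
#' @param a,b equal-length integer vectors of patterns in `{1, 2, 3}`.
#' @return A list with `n`, `n_concordant`, `pct_concordant` (rounded to
#'   the nearest integer), `n_discordant`, `pct_discordant`, and
#'   `discordant` (data.frame of off-diagonal `(a, b)` counts).
#' @export
concordance <- function(a, b) {
  a <- .asPatterns(a); b <- .asPatterns(b)
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  conc <- sum(a == b)
  tab <- table(factor(a, 1:3), factor(b, 1:3))
  off <- which(tab > 0 & row(tab) != col(tab), arr.ind = TRUE)
  disc <- data.frame(a = as.integer(off[, 1]), b = as.integer(off[, 2]),
                     count = tab[off])
  disc <- disc[order(disc$a, disc$b), , drop = FALSE]
  rownames(disc) <- NULL
  list(n = n, n_concordant = conc,
       pct_concordant = floor(100 * conc / n + 0.5),
       n_discordant = n - conc,
       pct_discordant = floor(100 * (n - conc) / n + 0.5),
       discordant = disc)
}

#' Cohen's kappa for two categorical raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o` the observed agreement and `p_e` the chance agreement from the
#' marginal products. When both raters use a single shared category
#' (`p_e = 1`), kappa is defined as 1 if the agreement is perfect.
#'
#' @param a,b equal-length vectors of categorical calls (any atomic type).
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohenKappa(c(1, 1, 2, 2), c(1, 2, 1, 2))   # 0: agreement at chance
#' @export
cohenKappa <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) == 0) stop("empty input")
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev)) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < 1e-12) {
    if (abs(po - 1) < 1e-12) return(1)
    stop("chance agreement is 1 but observed agreement is not")
  }
  (po - pe) / (1 - pe)
}

#' Mean pairwise kappa across several raters
#'
#' Agreement for three or more observers summarized as the arithmetic mean
#' of Cohen's kappa over all rater pairs.
#'
#' @param calls a data.frame or matrix, one column per rater, one row per
#'   case.
#' @return A list with `kappa` (mean pairwise) and `pairs` (data.frame of
#'   per-pair kappas).
#' @export
multiRaterKappa <- function(calls) {
  calls <- as.data.frame(calls)
  if (ncol(calls) < 2) stop("need at least two raters")
  cmb <- utils::combn(ncol(calls), 2)
  ks <- apply(cmb, 2, function(ij) cohenKappa(calls[[ij[1]]], calls[[ij[2]]]))
  list(kappa = mean(ks),
       pairs = data.frame(rater_a = colnames(calls)[cmb[1, ]],
                          rater_b = colnames(calls)[cmb[2, ]],
                          kappa = ks))
}
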