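# Geometry of the analysis rectangle over the invasive front.
#
# Conventions: image frame, um, origin top-left, y pointing down. For a
# travel direction t along the polyline, the "right" side on screen is
# (-t.y, t.x) and the "left" side is (t.y, -t.x).

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("degenerate tangent: zero-length segment")
  v / n
}

.sideVector <- function(tangent, side) {
  if (side == "right") c(-tangent[2], tangent[1])
  else c(tangent[2], -tangent[1])
}

# tangent of the ROI's local frame, recovered from the stored normal so
# that uvToPoint(pointToUV(p)) round-trips for either tumor side
.roiTangent <- function(roi) c(roi@normal[2], -roi@normal[1])

#' Place the analysis rectangle on an annotated invasive front
#'
#' Anchors a [RectangleROI-class] at a given arc-length position along the
#' front polyline. The local tangent is the direction of the segment
#' containing the anchor; when the anchor falls on an interior vertex, the
#' bisector of the adjacent segment directions is used, which keeps
#' normals stable on polylines. The normal is the unit vector
#' perpendicular to that tangent pointing into the tumor side, and the
#' front sits at `v = L/2` of the rectangle's local axis so that host
#' tissue occupies `[0, L/2]` and tumor `[L/2, L]`.
#'
#' @param front a [FrontAnnotation-class].
#' @param arcPosition position along the polyline in um, in
#'   `[0, arc length]`.
#' @param width,length,binWidth rectangle overrides in um; defaults give
#'   the standard 1 mm x 4 mm rectangle (4 mm^2) with 5 um bins.
#' @return A [RectangleROI-class] anchored on the front.
#' @examples
#' fr <- FrontAnnotation(cbind(c(-2000, 2000), c(0, 0)), "left")
#' roi <- buildROI(fr, arcPosition = 2000)
#' @export
buildROI <- function(front, arcPosition, width = 1000, length = 4000,
                     binWidth = 5) {
  stopifnot(is(front, "FrontAnnotation"))
  p <- front@points
  seg <- diff(p)
  segLen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(segLen))
  total <- cum[base::length(cum)]
  if (!is.finite(arcPosition) || arcPosition < 0 || arcPosition > total)
    stop(sprintf("arcPosition %.3f out of range [0, %.3f]",
                 arcPosition, total))
  # segment containing the arc position (the last one if at the very end)
  i <- findInterval(arcPosition, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(seg))
  frac <- (arcPosition - cum[i]) / segLen[i]
  anchor <- p[i, ] + frac * seg[i, ]
  atVertex <- function(k) abs(arcPosition - cum[k]) < 1e-9
  interior <- which(vapply(seq_len(nrow(p)), atVertex, logical(1)))
  interior <- interior[interior > 1 & interior < nrow(p)]
  tangent <- if (base::length(interior) == 1L) {
    k <- interior[1]
    .unit(.unit(seg[k - 1, ]) + .unit(seg[k, ]))
  } else {
    .unit(seg[i, ])
  }
  RectangleROI(anchor = anchor,
               normal = .sideVector(tangent, front@tumorSide),
               width = width, length = length, binWidth = binWidth)
}

#' Map image coordinates to the rectangle's local (u, v) frame
#'
#' `u` is the signed across-width coordinate (um along the front, zero on
#' the rectangle's axis); `v` runs along the 4 mm axis with the front at
#' `L/2` and values increasing into the tumor, so `v = 0` is the outer
#' (host) edge and `v = L` the inner (tumor) edge. Points outside the
#' rectangle simply map to out-of-range `(u, v)`.
#'
#' @param p numeric length-2 point, or an n x 2 matrix of points, in um.
#' @param roi a [RectangleROI-class].
#' @return For a single point, a named numeric `c(u =, v =)`; for a matrix,
#'   an n x 2 matrix with columns `u`, `v`.
#' @seealso [uvToPoint()] for the inverse, [roiContains()]
#' @export
pointToUV <- function(p, roi) {
  stopifnot(is(roi, "RectangleROI"))
  tang <- .roiTangent(roi)
  if (is.matrix(p)) {
    dx <- p[, 1] - roi@anchor[1]
    dy <- p[, 2] - roi@anchor[2]
    cbind(u = dx * tang[1] + dy * tang[2],
          v = roi@length / 2 + dx * roi@normal[1] + dy * roi@normal[2])
  } else {
    d <- p - roi@anchor
    c(u = sum(d * tang), v = roi@length / 2 + sum(d * roi@normal))
  }
}

#' Map local (u, v) coordinates back to the image frame
#'
#' Inverse of [pointToUV()].
#'
#' @param u,v local coordinates in um (vectors of equal length).
#' @param roi a [RectangleROI-class].
#' @return A length-2 numeric for scalar input, else an n x 2 matrix.
#' @export
uvToPoint <- function(u, v, roi) {
  stopifnot(is(roi, "RectangleROI"))
  tang <- .roiTangent(roi)
  x <- roi@anchor[1] + u * tang[1] + (v - roi@length / 2) * roi@normal[1]
  y <- roi@anchor[2] + u * tang[2] + (v - roi@length / 2) * roi@normal[2]
  if (base::length(u) == 1L) c(x, y) else cbind(x, y)
}

#' Test whether points fall inside the analysis rectangle
#'
#' A point is inside when `|u| <= W/2` and `0 <= v <= L`. Both outer
#' boundaries are included here; the half-open bin convention only matters
#' when counts are assigned to segments (see [binCounts()]).
#'
#' @param p length-2 point or n x 2 matrix, um.
#' @param roi a [RectangleROI-class].
#' @return Logical (vector for matrix input).
#' @export
roiContains <- function(p, roi) {
  uv <- pointToUV(p, roi)
  if (is.matrix(uv)) {
    abs(uv[, "u"]) <= roi@width / 2 & uv[, "v"] >= 0 & uv[, "v"] <= roi@length
  } else {
    abs(uv["u"]) <= roi@width / 2 && uv["v"] >= 0 && uv["v"] <= roi@length
  }
}

#' Corners of the analysis rectangle in image coordinates
#'
#' Returned in order (outer-left, outer-right, inner-right, inner-left)
#' with respect to the local frame; useful for drawing the ROI or writing
#' it as a GeoJSON polygon.
#'
#' @param roi a [RectangleROI-class].
#' @return A 4 x 2 numeric matrix of (x, y) um.
#' @export
roiCorners <- function(roi) {
  w2 <- roi@width / 2
  uvToPoint(c(-w2, w2, w2, -w2), c(0, 0, roi@length, roi@length), roi)
}
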