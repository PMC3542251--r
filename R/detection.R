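# Three-step detection of stain-positive lymphocytes:
# color thresholding -> watershed splitting -> size filtering.

#' Binary mask of candidate stain-positive pixels
#'
#' A pixel is candidate-positive when its brown (DAB) evidence exceeds the
#' red threshold and its counterstain evidence stays below the blue
#' threshold: `B < blueIntensity` and `R > redIntensity` and `R > B`. This
#' RGB rule separates brown chromogen from hematoxylin-blue nuclei and
#' unstained background using exactly the three tunables exposed to the
#' user.
#'
#' @param img an [IHCImage-class].
#' @param params a [DetectionParams-class].
#' @return An integer 0/1 matrix of the image's x-y dimensions.
#' @export
stainMask <- function(img, params = DetectionParams()) {
  stopifnot(is(img, "IHCImage"), is(params, "DetectionParams"))
  px <- img@pixels
  r <- px[, , 1]
  b <- px[, , 3]
  mask <- (b < params@blueIntensity) & (r > params@redIntensity) & (r > b)
  storage.mode(mask) <- "integer"
  mask
}

#' Split touching cells with a watershed on the distance transform
#'
#' Labels the connected components of a binary mask, separating touching
#' convex blobs at the saddle of the Euclidean distance transform. Basins
#' shallower than 0.5 um relative depth are merged and maxima are sought
#' in a 4 um-wide neighborhood (2 um half-width), so mildly irregular
#' single cells are not over-split while genuinely touching pairs (two
#' distance maxima) are divided.
#'
#' @param mask integer/logical matrix, as from [stainMask()].
#' @param mpp microns per pixel of the mask's source image.
#' @return An integer label matrix; 0 is background, labels `1..n` are
#'   objects.
#' @export
splitTouching <- function(mask, mpp) {
  stopifnot(is.matrix(mask), mpp > 0)
  if (!any(mask > 0)) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    return(lab)
  }
  d <- EBImage::distmap(mask) * mpp
  lab <- EBImage::watershed(d, tolerance = 0.5, ext = max(1L, round(2 / mpp)))
  lab <- as.matrix(EBImage::imageData(lab))
  storage.mode(lab) <- "integer"
  lab
}

#' Keep objects within the lymphocyte size range
#'
#' Converts labeled objects to detections, keeping those whose area lies in
#' `[sizeMin, sizeMax]` um^2. Centroids are means of member pixel centers,
#' reported in um; the intensity is the mean red-channel value over the
#' object when an intensity image is supplied.
#'
#' @param labels integer label matrix from [splitTouching()].
#' @param mpp microns per pixel.
#' @param params a [DetectionParams-class].
#' @param intensity optional numeric matrix (same dimensions) whose mean
#'   over each object fills the `intensity` column; NA otherwise.
#' @return A data.frame with columns `x_um`, `y_um`, `area_um2`,
#'   `intensity`, one row per kept object, ordered by label.
#' @export
sizeFilter <- function(labels, mpp, params = DetectionParams(),
                       intensity = NULL) {
  stopifnot(is.matrix(labels), mpp > 0, is(params, "DetectionParams"))
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), intensity = numeric(0))
  if (!any(labels > 0)) return(empty)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  npix <- tabulate(lab)
  areas <- npix * mpp^2
  keep <- which(npix > 0 & areas >= params@sizeMin & areas <= params@sizeMax)
  if (length(keep) == 0) return(empty)
  sel <- lab %in% keep
  lab <- lab[sel]
  idx <- idx[sel, , drop = FALSE]
  cx <- rowsum((idx[, 1] - 0.5) * mpp, lab) / npix[keep]
  cy <- rowsum((idx[, 2] - 0.5) * mpp, lab) / npix[keep]
  ii <- if (is.null(intensity)) rep(NA_real_, length(keep))
        else as.vector(rowsum(intensity[cbind(idx[, 1], idx[, 2])], lab) /
                       npix[keep])
  data.frame(x_um = as.vector(cx), y_um = as.vector(cy),
             area_um2 = areas[keep], intensity = ii)
}

#' Detect stain-positive lymphocytes inside an analysis rectangle
#'
#' Composes [stainMask()], [splitTouching()] and [sizeFilter()] over the
#' part of the image covered by the rectangle. Objects straddling the ROI
#' edge are kept if and only if their centroid falls inside the rectangle
#' (an unbiased counting rule). The result is fully deterministic for
#' fixed inputs.
#'
#' @param img an [IHCImage-class]; the ROI must lie within its bounds.
#' @param roi a [RectangleROI-class].
#' @param params a [DetectionParams-class].
#' @return A data.frame of detections (`x_um`, `y_um`, `area_um2`,
#'   `intensity`) in image coordinates, ordered by position.
#' @examples
#' truth <- simulateSlide(SimulationConfig(3), seed = 1,
#'                        roiDims = c(width = 200, length = 1000))
#' roi <- buildROI(truth@front, arcPosition = 100,
#'                 width = 200, length = 1000)
#' dets <- detectCells(truthImage(truth), roi)
#' @export
detectCells <- function(img, roi, params = DetectionParams()) {
  stopifnot(is(img, "IHCImage"), is(roi, "RectangleROI"))
  d <- dim(img@pixels)
  lim <- c(d[1], d[2]) * img@mpp
  corners <- roiCorners(roi)
  if (any(corners[, 1] < -1e-6 | corners[, 1] > lim[1] + 1e-6 |
          corners[, 2] < -1e-6 | corners[, 2] > lim[2] + 1e-6))
    stop("roi exceeds image bounds")
  # crop to the ROI's bounding box, padded by one max-size object diameter
  pad <- 2 * sqrt(params@sizeMax / pi)
  i0 <- max(1L, floor(max(0, min(corners[, 1]) - pad) / img@mpp) + 1L)
  i1 <- min(d[1], ceiling(min(lim[1], max(corners[, 1]) + pad) / img@mpp))
  j0 <- max(1L, floor(max(0, min(corners[, 2]) - pad) / img@mpp) + 1L)
  j1 <- min(d[2], ceiling(min(lim[2], max(corners[, 2]) + pad) / img@mpp))
  sub <- IHCImage(img@pixels[i0:i1, j0:j1, , drop = FALSE], img@mpp)
  mask <- stainMask(sub, params)
  labels <- splitTouching(mask, img@mpp)
  dets <- sizeFilter(labels, img@mpp, params,
                     intensity = sub@pixels[, , 1])
  if (nrow(dets) > 0) {
    dets$x_um <- dets$x_um + (i0 - 1L) * img@mpp
    dets$y_um <- dets$y_um + (j0 - 1L) * img@mpp
    dets <- dets[roiContains(cbind(dets$x_um, dets$y_um), roi), ,
                 drop = FALSE]
    dets <- dets[order(dets$x_um, dets$y_um), , drop = FALSE]
    rownames(dets) <- NULL
  }
  dets
}
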