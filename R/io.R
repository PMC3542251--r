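# File formats: GeoJSON for front/ROI annotations, CSV for detections,
# profiles and cohort tables, JSON for pattern reports, TIFF/PNG rasters.
# All coordinates on disk are um, image frame (origin top-left, y down);
# real values are written with 17 significant digits so round-trips are
# exact to floating-point resolution.

.fmt <- function(x) formatC(as.numeric(x), digits = 17, format = "g")

#' Read and write front annotations as GeoJSON
#'
#' The front is a GeoJSON `LineString` feature with a `tumor_side`
#' property; the microns-per-pixel of the source image may be recorded in
#' a top-level `mpp` property. Coordinates are um in the image frame.
#'
#' @param front a [FrontAnnotation-class].
#' @param path file path.
#' @param mpp optional microns-per-pixel to record.
#' @return `readFrontGeoJSON` returns a [FrontAnnotation-class] (with an
#'   `mpp` attribute when the file records one); `writeFrontGeoJSON`
#'   returns `path` invisibly.
#' @export
writeFrontGeoJSON <- function(front, path, mpp = NULL) {
  stopifnot(is(front, "FrontAnnotation"))
  obj <- list(
    type = "FeatureCollection",
    mpp = mpp,
    features = list(list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = unname(apply(front@points, 1, c,
                                                 simplify = FALSE))),
      properties = list(tumor_side = front@tumorSide, units = "um")
    )))
  if (is.null(mpp)) obj$mpp <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFrontGeoJSON
#' @export
readFrontGeoJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  feat <- obj$features[[1]]
  if (is.null(feat) || !identical(feat$geometry$type, "LineString"))
    stop("expected a GeoJSON LineString feature in ", path)
  pts <- do.call(rbind, lapply(feat$geometry$coordinates,
                               function(p) c(p[[1]], p[[2]])))
  side <- feat$properties$tumor_side
  if (is.null(side)) stop("missing tumor_side property in ", path)
  fr <- FrontAnnotation(pts, tumorSide = side)
  if (!is.null(obj$mpp)) attr(fr, "mpp") <- obj$mpp
  fr
}

#' Read and write analysis rectangles as GeoJSON
#'
#' The rectangle is a GeoJSON `Polygon` of its four corners, with the
#' defining `anchor`, `normal`, `width_um`, `length_um` and `bin_um`
#' recorded as properties so the read-back object is exact, not
#' reconstructed from corners.
#'
#' @param roi a [RectangleROI-class].
#' @param path file path.
#' @param mpp optional microns-per-pixel to record.
#' @return `readROIGeoJSON` returns a [RectangleROI-class];
#'   `writeROIGeoJSON` returns `path` invisibly.
#' @export
writeROIGeoJSON <- function(roi, path, mpp = NULL) {
  stopifnot(is(roi, "RectangleROI"))
  corners <- roiCorners(roi)
  ring <- unname(apply(rbind(corners, corners[1, ]), 1, c,
                       simplify = FALSE))
  obj <- list(
    type = "FeatureCollection",
    mpp = mpp,
    features = list(list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(anchor = roi@anchor, normal = roi@normal,
                        width_um = roi@width, length_um = roi@length,
                        bin_um = roi@binWidth, units = "um")
    )))
  if (is.null(mpp)) obj$mpp <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeROIGeoJSON
#' @export
readROIGeoJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  pr <- obj$features[[1]]$properties
  if (is.null(pr$anchor) || is.null(pr$normal))
    stop("missing anchor/normal properties in ", path)
  RectangleROI(anchor = unlist(pr$anchor), normal = unlist(pr$normal),
               width = pr$width_um, length = pr$length_um,
               binWidth = pr$bin_um)
}

#' Read and write density profiles as CSV
#'
#' Columns are `v_um` (bin left edge), `offset_um` (signed distance from
#' the front, negative outside the tumor) and `density_per_5000um2`.
#' Curve-level metadata (`n_rectangles`, `width_used_um`) travels in `#`
#' comment lines above the header.
#'
#' @param p a [DensityProfile-class].
#' @param path file path.
#' @return `readProfileCSV` returns a [DensityProfile-class];
#'   `writeProfileCSV` returns `path` invisibly.
#' @export
writeProfileCSV <- function(p, path) {
  stopifnot(is(p, "DensityProfile"))
  v <- .binLeft(p)
  front <- (min(p@binEdges) + max(p@binEdges)) / 2
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# density profile: coordinates um, origin image top-left, y down",
    sprintf("# n_rectangles=%s", .fmt(p@nRectangles)),
    sprintf("# width_used_um=%s", .fmt(p@widthUsed)),
    "v_um,offset_um,density_per_5000um2",
    sprintf("%s,%s,%s", .fmt(v), .fmt(v - front), .fmt(p@density))), con)
  invisible(path)
}

#' @rdname writeProfileCSV
#' @export
readProfileCSV <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getMeta <- function(key, default) {
    hit <- grep(sprintf("^# %s=", key), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(".*=", "", hit[1])) else default
  }
  df <- read.csv(text = lines[!grepl("^#", lines)])
  need <- c("v_um", "density_per_5000um2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed profile CSV ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(df) < 2 || anyNA(df$v_um) || anyNA(df$density_per_5000um2))
    stop("malformed profile CSV ", path, ": truncated or non-numeric rows")
  dv <- diff(df$v_um)
  if (any(abs(dv - dv[1]) > 1e-6))
    stop("malformed profile CSV ", path, ": v_um is not evenly spaced")
  DensityProfile(density = df$density_per_5000um2,
                 binEdges = c(df$v_um, df$v_um[nrow(df)] + dv[1]),
                 nRectangles = getMeta("n_rectangles", 1),
                 widthUsed = getMeta("width_used_um", 1000))
}

#' Read and write detection tables as CSV
#'
#' Columns `x_um`, `y_um`, `area_um2`, `intensity`, as produced by
#' [detectCells()].
#'
#' @param dets detections data.frame.
#' @param path file path.
#' @return `readDetectionsCSV` returns the data.frame;
#'   `writeDetectionsCSV` returns `path` invisibly.
#' @export
writeDetectionsCSV <- function(dets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("x_um,y_um,area_um2,intensity",
               sprintf("%s,%s,%s,%s", .fmt(dets$x_um), .fmt(dets$y_um),
                       .fmt(dets$area_um2), .fmt(dets$intensity))), con)
  invisible(path)
}

#' @rdname writeDetectionsCSV
#' @export
readDetectionsCSV <- function(path) {
  df <- read.csv(path)
  need <- c("x_um", "y_um", "area_um2", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed detections CSV ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

#' Read and write cohort tables as CSV
#'
#' One row per patient: `patient_id`, `pattern_cd3`, optionally
#' `pattern_cd45r0` and any number of `rater_*` columns of per-observer
#' calls.
#'
#' @param tab cohort data.frame.
#' @param path file path.
#' @return `readCohortCSV` returns the data.frame; `writeCohortCSV`
#'   returns `path` invisibly.
#' @export
writeCohortCSV <- function(tab, path) {
  stopifnot(is.data.frame(tab), "patient_id" %in% names(tab))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  df <- read.csv(path)
  if (!"patient_id" %in% names(df))
    stop("malformed cohort CSV ", path, ": missing patient_id column")
  if (anyDuplicated(df$patient_id))
    stop("malformed cohort CSV ", path, ": duplicate patient_id values")
  df
}

#' Serialize a pattern call as a JSON report
#'
#' Writes the pattern, the peak location/height, the window means, which
#' cascade rule fired, and an echo of the classifier configuration.
#'
#' @param call a [PatternCall-class].
#' @param path file path.
#' @param cfg the [ClassifierConfig-class] used (echoed into the report).
#' @return `path`, invisibly.
#' @export
writePatternJSON <- function(call, path, cfg = ClassifierConfig()) {
  obj <- list(pattern = call@pattern,
              peak_offset_um = call@peakOffset,
              peak_height = call@peakHeight,
              m_in = call@mIn, m_out = call@mOut,
              rule_fired = call@ruleFired,
              degenerate = call@degenerate,
              config = list(tau_low = cfg@tauLow, rho_in = cfg@rhoIn,
                            pi_peak = cfg@piPeak,
                            window_bins = cfg@windowBins,
                            tumor_core_um = cfg@tumorCore,
                            peritumoral_um = cfg@peritumoral,
                            margin_um = cfg@margin))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read and write calibrated RGB images
#'
#' TIFF or PNG via EBImage, converted to the package's 0-255 RGB array
#' convention. Because standard rasters carry no physical calibration,
#' the microns-per-pixel value is taken from an `mpp` argument or from a
#' plain-text sidecar file `<path>.mpp` (written automatically by
#' `writeIHCImage`).
#'
#' @param path image file path (.tif/.tiff/.png).
#' @param mpp microns per pixel; when NULL, read from the sidecar.
#' @param img an [IHCImage-class].
#' @return `readIHCImage` returns an [IHCImage-class]; `writeIHCImage`
#'   returns `path` invisibly.
#' @export
readIHCImage <- function(path, mpp = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (is.null(mpp)) {
    sidecar <- paste0(path, ".mpp")
    if (!file.exists(sidecar))
      stop("no mpp given and no sidecar file ", sidecar)
    mpp <- as.numeric(readLines(sidecar, n = 1))
  }
  im <- EBImage::readImage(path)
  px <- EBImage::imageData(im) * 255
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] != 3L) stop("expected an RGB image: ", path)
  IHCImage(px, mpp)
}

#' @rdname readIHCImage
#' @export
writeIHCImage <- function(img, path) {
  stopifnot(is(img, "IHCImage"))
  im <- EBImage::Image(img@pixels / 255, colormode = "Color")
  EBImage::writeImage(im, path)
  writeLines(.fmt(img@mpp), paste0(path, ".mpp"))
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' A single YAML file with per-stage sections (`detection`, `classifier`,
#' `geometry`, `smoothing`, `seed`, `out_dir`), each optional; missing
#' values fall back to package defaults. Returns validated parameter
#' objects ready for [runPipeline()].
#'
#' @param path YAML file path; NULL gives all defaults.
#' @return A list with `detection` ([DetectionParams-class]), `classifier`
#'   ([ClassifierConfig-class]), `geometry` (list of width/length/bin
#'   overrides), `windowBins`, `seed`, `outDir`.
#' @export
readRunConfig <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  pick <- function(section, key, default) {
    v <- raw[[section]][[key]]
    if (is.null(v)) default else v
  }
  det <- DetectionParams(
    sizeMin = pick("detection", "size_min_um2", 15),
    sizeMax = pick("detection", "size_max_um2", 150),
    blueIntensity = pick("detection", "blue_intensity", 160),
    redIntensity = pick("detection", "red_intensity", 100))
  cls <- ClassifierConfig(
    tauLow = pick("classifier", "tau_low", 3),
    rhoIn = pick("classifier", "rho_in", 1.5),
    piPeak = pick("classifier", "pi_peak", 2),
    windowBins = pick("classifier", "window_bins", 21),
    tumorCore = unlist(pick("classifier", "tumor_core_um", c(2500, 4000))),
    peritumoral = unlist(pick("classifier", "peritumoral_um", c(0, 1500))),
    margin = unlist(pick("classifier", "margin_um", c(1400, 2400))))
  list(detection = det, classifier = cls,
       geometry = list(width = pick("geometry", "width_um", 1000),
                       length = pick("geometry", "length_um", 4000),
                       binWidth = pick("geometry", "bin_um", 5)),
       windowBins = pick("smoothing", "window_bins", 21),
       seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed),
       outDir = raw$out_dir)
}
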