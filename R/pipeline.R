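# End-to-end pipeline: detect -> profile per rectangle -> merge -> smooth
# -> classify, with optional on-disk reports and a reproduction manifest.

#' Run the full quantification pipeline on one slide
#'
#' For each requested arc position a rectangle is placed on the front,
#' cells are detected inside it, counts are binned and standardized; the
#' per-rectangle curves are merged into a mean curve, smoothed, and
#' classified. The run is deterministic given its inputs. When `outDir`
#' is given, all intermediates (per-rectangle detection CSVs, merged
#' profile CSV, pattern JSON) and a manifest (inputs, configuration hash,
#' package version) are written there.
#'
#' @param image an [IHCImage-class], or a raster path readable by
#'   [readIHCImage()].
#' @param front a [FrontAnnotation-class], or a GeoJSON path.
#' @param arcPositions numeric vector of arc-length positions (um) along
#'   the front at which to place rectangles; at least one. How many
#'   rectangles fit a slide (typically 2-8) and their spacing is the
#'   caller's choice.
#' @param cfg a run configuration as returned by [readRunConfig()]
#'   (defaults to package defaults).
#' @param mpp microns per pixel, only needed when `image` is a path with
#'   no sidecar.
#' @param outDir optional output directory.
#' @return A list with `call` (the [PatternCall-class]), `profile` (the
#'   smoothed merged [DensityProfile-class]), `rawProfile`, `rois`,
#'   `detections` (list of per-rectangle data.frames), and `manifest`.
#' @examples
#' truth <- simulateSlide(SimulationConfig(3), seed = 7,
#'                        roiDims = c(width = 300, length = 1000))
#' cfg <- readRunConfig()
#' cfg$geometry <- list(width = 300, length = 1000, binWidth = 5)
#' res <- runPipeline(truthImage(truth), truth@front,
#'                    arcPositions = 150, cfg = cfg)
#' @export
runPipeline <- function(image, front, arcPositions, cfg = readRunConfig(),
                        mpp = NULL, outDir = cfg$outDir) {
  inputs <- list(
    image = if (is.character(image)) image else "<in-memory>",
    front = if (is.character(front)) front else "<in-memory>")
  if (is.character(image)) image <- readIHCImage(image, mpp = mpp)
  if (is.character(front)) front <- readFrontGeoJSON(front)
  stopifnot(is(image, "IHCImage"), is(front, "FrontAnnotation"))
  if (length(arcPositions) < 1) stop("need at least one arc position")
  geo <- cfg$geometry
  rois <- lapply(arcPositions, function(a)
    buildROI(front, a, width = geo$width, length = geo$length,
             binWidth = geo$binWidth))
  detections <- lapply(rois, function(roi)
    detectCells(image, roi, params = cfg$detection))
  profiles <- mapply(function(dets, roi) toDensity(binCounts(dets, roi), roi),
                     detections, rois, SIMPLIFY = FALSE)
  raw <- mergeProfiles(profiles)
  smoothed <- smoothProfile(raw, cfg$windowBins)
  call <- classifyProfile(raw, cfg$classifier)
  manifest <- list(
    inputs = inputs,
    arc_positions_um = arcPositions,
    geometry = geo,
    detection = list(size_min_um2 = cfg$detection@sizeMin,
                     size_max_um2 = cfg$detection@sizeMax,
                     blue_intensity = cfg$detection@blueIntensity,
                     red_intensity = cfg$detection@redIntensity),
    smoothing_window_bins = cfg$windowBins,
    seed = cfg$seed,
    package_version = as.character(packageVersion("lqli")))
  manifest$config_md5 <- .md5Of(manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(detections))
      writeDetectionsCSV(detections[[k]],
                         file.path(outDir, sprintf("detections_roi%02d.csv", k)))
    writeProfileCSV(raw, file.path(outDir, "profile_mean.csv"))
    writeProfileCSV(smoothed, file.path(outDir, "profile_smoothed.csv"))
    writePatternJSON(call, file.path(outDir, "pattern.json"),
                     cfg = cfg$classifier)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(call = call, profile = smoothed, rawProfile = raw, rois = rois,
       detections = detections, manifest = manifest)
}

.md5Of <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}
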