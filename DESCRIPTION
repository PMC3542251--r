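Package: lqli
Title: Linear Quantification of Lymphoid Infiltration at the Tumor
    Invasive Margin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of stained lymphocytes across the
    invasive margin of solid tumors on immunohistochemistry images.
    Detects DAB-positive cells by color thresholding, watershed splitting
    and size filtering; bins detections into 5 micrometer segments along
    an axis perpendicular to an annotated invasive front; standardizes
    counts to cells per 5000 square micrometers; merges and smooths
    density-versus-distance curves; and classifies each tumor into one of
    three infiltration patterns (high intratumoral density, peri-marginal
    peak, uniform low density). Includes cohort-level summaries
    (pattern frequencies, dual-marker concordance, Cohen's kappa for
    interobserver agreement), a tissue-microarray core sampling emulator,
    and a synthetic slide generator with ground-truth centroids so the
    whole pipeline is testable without real histology data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'geometry.R'
    'detection.R'
    'profiling.R'
    'classification.R'
    'cohort.R'
    'synthetic_data.R'
    'io.R'
    'pipeline.R'
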