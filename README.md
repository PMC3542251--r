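# lqli

Linear quantification of lymphoid infiltration (LQLI) at the tumor
invasive margin, for pathologists and image-analysis researchers working
with immunohistochemistry (IHC) virtual slides.

Lymphocyte infiltration predicts outcome in colorectal and other solid
carcinomas, but single counts in small areas (0.6 mm tissue-microarray
cores) are unreliable because the infiltrate is heterogeneous. LQLI
instead measures the *profile* of infiltration: stained cells are
counted in 5 µm segments along a 4 mm axis perpendicular to the tumor's
invasive front, over a 1 mm × 4 mm rectangle (4 mm², >14× a TMA core).
Counts are standardized to cells per 5000 µm², giving a density curve
`d(v)` over `v ∈ [0, 4000]` µm with the front at `v = 2000` (host
tissue left, tumor right). Curves from 2–8 rectangles are averaged and
the mean curve is classified into one of three patterns:

* **Pattern 1** — high density *within* the tumor,
* **Pattern 2** — a density peak near the invasive margin (typically
  ~400 µm ahead of the front, heights ~3–14 cells/5000 µm²),
* **Pattern 3** — uniform low density.

The package implements the whole pipeline in Bioconductor-style S4:

| stage | functions |
|---|---|
| geometry | `FrontAnnotation`, `buildROI`, `pointToUV`, `roiContains` |
| detection | `stainMask`, `splitTouching`, `sizeFilter`, `detectCells` |
| profiling | `binCounts`, `toDensity`, `mergeProfiles`, `smoothProfile`, `minmaxRatio`, `peakStats` |
| classification | `classifyProfile`, `classifyCohort`, `ClassifierConfig` |
| cohort statistics | `patternFrequencies`, `concordance`, `cohenKappa`, `multiRaterKappa` |
| synthetic data | `SimulationConfig`, `simulateProfile`, `simulatePoints`, `simulateSlide`, `simulateCohort`, `simulateTMADensity`, `matchCentroids` |
| pipeline & IO | `runPipeline`, `readRunConfig`, CSV/GeoJSON/JSON/PNG-TIFF readers and writers |

Detection is the classical three-step recipe — color thresholding
(brown DAB vs blue hematoxylin, thresholds `blue_intensity` /
`red_intensity`), watershed splitting of touching cells on the distance
transform, and size filtering (15–150 µm² by default). A synthetic
slide generator draws cells from an inhomogeneous Poisson process whose
intensity follows the three patterns and renders them as stained discs
with ground-truth centroids, so every stage is testable without any
real histology data. A thin command-line tool (`exec/lqli`) exposes
`detect`, `profile`, `classify`, `cohort`, `simulate` and `run`
subcommands over the same functions.

## Worked example

Simulate a pattern-2 slide, detect cells, build and classify the curve:

```r
library(lqli)

truth <- simulateSlide(SimulationConfig(2), seed = 42)   # 1 x 4 mm, 1 um/px
roi   <- buildROI(truth@front, arcPosition = 500)
dets  <- detectCells(truthImage(truth), roi)
nrow(dets)
#> [1] 1892

m <- matchCentroids(dets, truthCentroids(truth))
round(c(recall = m$recall, precision = m$precision), 4)
#>    recall precision
#>    0.9638    1.0000

profile <- toDensity(binCounts(dets, roi), roi)
classifyProfile(profile)
#> PatternCall: pattern 2 (R2)
#>   peak 7.10 cells/5000 um^2 at -405 um from front; m_in 2.37, m_out 1.89
```

The call reports the pattern, which cascade rule fired (`R2`: a
marginal peak at least 3 cells/5000 µm² and twice the baseline), the
peak height and its offset from the front (negative = outside the
tumor), and the mean densities inside (`m_in`) and outside (`m_out`)
the tumor. Cohort-level summaries work on vectors of such calls:

```r
patternFrequencies(c(rep(1, 24), rep(2, 71), rep(3, 22)))
#>   pattern count percent
#> 1       1    24      21
#> 2       2    71      61
#> 3       3    22      19

cohenKappa(c(1, 1, 2, 2), c(1, 2, 1, 2))
#> [1] 0
```

See `vignettes/lqli-methods.Rmd` for the models, calibrations and
design decisions.

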