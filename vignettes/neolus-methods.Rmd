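---
title: "Methods: texture-based classification of neonatal lung ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture-based classification of neonatal lung ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neolus)
```

## The problem

Neonatal lung ultrasound (LUS) is read almost entirely through artifacts:
the pleural line, horizontal A-line reverberations, vertical B-lines,
and hypoechoic consolidations. Which artifacts appear, and how, maps onto
the six pathology classes handled here: Normal, transient tachypnea of
the newborn (TTN), pneumothorax (PTX), respiratory distress syndrome
(RDS), chronic lung disease (CLD) and consolidation (CON). `neolus`
implements a classical, interpretable pipeline for this six-way task:
multiscale oriented decomposition, texture descriptors, univariate
selection, and a linear discriminant classifier evaluated with
cross-validation schemes that respect subject structure.

Clinical neonatal LUS data is access-restricted, so the package also
ships a seeded phantom generator that emulates the canonical
morphologies. Everything downstream of the generator is agnostic to
whether frames are clinical or synthetic.

## Pipeline and assumptions

### Preprocessing

Bright overlay artifacts (probe marks, annotations) sit at fixed
coordinates within a video. `remove_artifacts()` operates inside
caller-supplied rectangles: pixels strictly above half of the ROI
maximum are selected, their 8-connected neighbours are added, and the
selection is replaced by the ROI median. Two numerical choices matter:

* the median is computed over the *original* ROI values, before any
  replacement, so the result does not depend on pixel visit order;
* for even counts the lower median is used, keeping replacements on the
  attained 8-bit intensity grid.

Note a consequence of the strictly-greater-than rule: the maximum pixel
always exceeds half of itself, so any ROI with a nonzero maximum has a
nonempty selection. The operation is idempotent on flattened regions
(re-running replaces a uniform selection with its own median).

`normalize_geometry()` resamples every frame to 520 x 420 (rows x
columns) with bilinear interpolation — monotone and overshoot-free, so
the intensity range never expands — then trims ten pixels from every
border, giving the fixed 500 x 400 working raster. Only the quantified
border trim is implemented; free-form cropping of "unimportant parts"
would require per-frame judgment that a reproducible pipeline should not
exercise silently.

### Dual-tree complex wavelet decomposition

`dtcwt_forward()` decomposes the frame to five levels with two parallel
separable filter-bank trees whose cross-combinations yield six complex
oriented subbands per level (about +15, +45, +75, -75, -45, -15 degrees)
plus a per-level low-pass raster:

* **Level 1** uses the near-symmetric biorthogonal pair with a 5-tap
  scaling filter and 7-tap wavelet filter, applied without decimation;
  the even/odd polyphase components of the filtered image are the two
  trees. The filter constants satisfy the halfband
  perfect-reconstruction identity exactly.
* **Levels 2+** use the orthonormal 14-tap quarter-shift pair; the
  second tree's filters are the time reverse of the first tree's, so
  their group delays differ by half a sample at the doubled rate. This
  is what makes subband *magnitudes* nearly shift invariant, and it is
  why features are computed on magnitudes rather than real or imaginary
  parts (a documented choice; the alternative readings are not exposed
  because they reintroduce shift sensitivity).
* **Boundaries** use symmetric (edge-repeating) extension, folding as
  often as needed so deep levels of small rasters stay defined; odd
  rasters are padded by one replicated row/column before each split.
* **Normalization.** Level-1 outputs are scaled by sqrt(2) per dimension
  and the four-tree-to-two-complex combination is orthonormal, so on
  band-limited speckle fields the total energy of subband magnitudes
  plus final low-pass is within about 20% of the input energy. The
  transform is 4x redundant, so images dominated by strong coherent
  structure (bright lines) can exceed input energy; the energy check in
  the test suite therefore uses pure speckle fields, which is also the
  background texture the features see everywhere outside morphologies.
* **Per-level low-pass `M_j`** is the average of the four trees'
  scaling rasters at level `j`, captured during the recursion. This
  makes global low-pass summaries (for example the mean of the
  second-level low-pass band, historically one of the most
  class-informative features: aerated lungs are dark below the pleura,
  B-line-filled lungs are bright) available at every depth.

The shift-variance probe `shift_variance_metric()` summarizes each
subband by block-wise magnitude energies (4 x 4 blocks) and measures the
relative change under a one-pixel translation; blocks make the metric
sensitive to the spatial redistribution a critically-sampled DWT suffers
while tolerating the sub-pixel drift a quarter-sample-aligned transform
exhibits. The plain DWT baseline (`dwt_forward()`) exists only for this
comparison.

### Texture features

Every raster from `magnitude_subimages()` is split into top and bottom
halves (`split_rois()`, floor convention): the top half carries
pleural-line content, the bottom half A-line/B-line content. Low-pass
rasters additionally contribute full-extent features. Per region:

* **Statistical (5)** — mean, population SD, skewness, excess kurtosis,
  entropy. The SD is the population standard deviation
  `sqrt(sum((x - mean)^2) / (n m))`: the printed form dividing the root
  by `n m` is dimensionally inconsistent with the standardized moments
  that follow, so the moment-consistent form is implemented. Entropy
  treats the region as a distribution (values divided by their sum,
  `0 log 0 := 0`); a 256-bin histogram entropy is available via
  `feature_config(entropy = "histogram")`.
* **GLCM (5 features x 6 offsets)** — contrast, correlation, energy,
  homogeneity, entropy on 8-level equal-width quantization with
  directional offsets (0,1), (1,0), (0,2), (2,0), (1,1), (2,2).
  Correlation divides by the mean and population variance of the
  quantized region itself, following the source formulation; the
  textbook marginal-moment form is a config switch
  (`glcm_correlation = "marginal"`).
* **GLRLM (11 features x 4 directions)** — the classical run-length
  statistics at 0, 45, 90, 135 degrees, on the same 8-level
  quantization as the GLCM (the quantization for run lengths is
  unstated in the source; sharing it keeps the two families on one
  grey scale). All denominators are the run count except run
  percentage, which divides by the pixel count.
* **LBP (10)** — rotation-invariant uniform local binary patterns,
  8 neighbours at radius 1 taken from the 3 x 3 ring without
  interpolation, neighbour >= centre mapping to 1; nine uniform
  rotation classes plus one non-uniform catch-all, normalized to sum 1.

GLCM/GLRLM features are emitted per offset/direction rather than
averaged (averaging is `feature_config(average_glcm = TRUE)`); per-offset
emission preserves anisotropy, which is exactly what distinguishes
horizontal A-line texture from vertical B-line texture. Whether halves
should apply to oriented subbands as well as low-pass bands is not
specified by the source; they are applied to all rasters, which
subsumes the narrower reading. With five levels this gives
`(35 rasters x 2 halves + 5 full) x 89 = 6675` image features plus the
three clinical covariates: gestational age (weeks), cumulative
gestational age at scan (weeks), days of life (days). The clinical
triple is always appended and never enters feature selection: it is the
domain's prior knowledge, not a candidate.

Degenerate inputs: a zero-SD region returns skewness/kurtosis 0 with a
`degenerate` attribute; quantization treats ranges at rounding-noise
scale (`<= 1e-12` relative) as constant so that the all-zero subbands of
degenerate frames do not produce noise-driven texture.

### Selection and classification

`chi2_rank()` discretizes each image feature into 10 quantile bins
(computed on the rows given to it — inside cross-validation, the
training rows only) and tests independence against the class labels
with Pearson's chi-square; features are ranked by ascending p-value,
ties broken by column order, constants ranked last with p = 1. Quantile
binning was chosen over fixed-range binning because feature families
span orders of magnitude and quantiles make the test scale-invariant;
ten bins keeps expected cell counts above ~5 at the fold sizes used.
The default `k = 15` image features plus the 3 clinical covariates keeps
the model dimension at 10-15% of training-fold size — deliberately
conservative against overfitting.

`fit_lda()` is pooled-covariance linear discriminant analysis with:

* training-fold standardization (unstated in the source; necessary
  because contrast-type and energy-type features differ by orders of
  magnitude),
* a ridge `1e-6 * trace(Sigma)/d` on the pooled covariance so folds
  with nearly collinear selected features stay well-posed,
* priors equal across classes (balanced cohorts) or proportional to
  training counts (imbalanced cohorts).

`run_loo_cv()` and `run_loso_cv()` refit the entire selection +
standardization + LDA chain inside every fold; ranking on anything but
the training rows is a leakage bug, and the test suite asserts that a
feature informative only in held-out rows cannot influence the ranking.
The LOSO scheme folds by subject and computes accuracy over all images,
the only reading consistent with row-percentage confusion reporting.

### Metrics and printed-table reconstruction

`metrics_from_confusion()` returns overall accuracy
(`100 * trace / total`) and class-size-weighted F1. Published reference
results for this task are row percentages rounded to two decimals;
`counts_from_rowpct()` reconstructs integer counts by nearest-cell
rounding repaired to exact row totals with the largest-remainder rule —
the integer matrix closest to the printed cells. Reconstructing the
four reference settings reproduces all four published accuracies to
within rounding. Of the four published weighted-F1 values, the two
middle ones (imbalanced LOO and balanced LOSO) are inconsistent with
their own matrices and consistent with each other's — they appear
swapped in print; the package reports the matrix-implied values, under
which all four published F1 numbers are reproduced.

## The phantom generator

`render_phantom()` draws morphologies on an echo map (brightest
structure wins where they overlap, and B-lines erase A-lines as they do
physically), then multiplies by a mean-normalized, box-smoothed
Rayleigh field — the standard minimal surrogate for fully developed,
slightly correlated ultrasound speckle. Defaults per class follow the
morphology grid: Normal (thin regular pleura + 4 A-lines), PTX (enhanced
A-lines, slower decay), TTN (separate B-lines + double lung point), RDS
(thick irregular pleura + coalescent B-lines + small consolidation),
CLD (thick irregular pleura + mixed B-lines, no consolidation), CON
(large rimmed consolidation). Geometry defaults (70 px A-line spacing,
10 px separate B-line width, 0.13 H pleural depth on the 520 x 420
canvas) were chosen once to look like linear-probe neonatal frames at
that raster size and are not tuned thereafter.

Clinical covariates are drawn per subject: CLD with GA 24-28 wk and DOL
28-90 d, RDS with GA 24-32 wk and DOL 0-7 d, TTN with GA 34-41 wk and
DOL 0-3 d, and Normal/PTX/CON uniform over GA 24-41 wk, DOL 0-28 d,
with CGATS = GA + DOL/7. This reproduces the clinically reported
structure that the covariates separate CLD from RDS (and TTN) but carry
no information about Normal versus PTX, which must be distinguished by
image texture alone.

`generate_cohort()` mirrors the balanced design: subjects per class,
six videos per subject (one per lung region R1-R3, L1-L3), frames per
video sharing the subject's jittered specification up to a +/- 2 px
translation and fresh speckle. All randomness descends from one master
seed; identical seeds reproduce cohorts bit for bit.

**What the phantoms do not emulate** — curvilinear probe geometry,
depth-dependent attenuation and focusing, rib shadows, lung sliding and
any temporal dynamics, inter-observer acquisition variability, and the
intra-class morphological ambiguity that makes real TTN overlap with
Normal, PTX and RDS. Phantom classes are constructed to be separable, so
passing the synthetic end-to-end checks demonstrates that the pipeline
is implemented correctly and leak-free — not that these accuracy levels
transfer to clinical data, whose published accuracies are lower
precisely because real classes overlap.

## Problem sizes and runtime choices

The synthetic experiments in the tests and the acceptance script use the
published balanced design (4 subjects per class x 6 videos x 5 frames =
720 images of 520 x 420, normalized to 500 x 400) for the end-to-end
checks, 16 x 16 rasters for the brute-force oracle comparisons (50
seeded repetitions, relative tolerance 1e-9), 96 x 80 smoothed-speckle
fields for the 50-fixture shift-invariance comparison, and 1000-feature
tables with 360 samples for selection-sanity rates. Pixel-level counting
kernels (separable filtering, co-occurrence pair counts, run scans, LBP
codes, per-fold chi-square scans) are compiled; the public R operations
remain the reference implementations, and the test suite asserts the
compiled batched paths agree with them exactly.

## Known limitations

* Phantom realism is calibrated only to qualitative morphology
  descriptions; no quantitative intensity statistics for real LUS
  morphologies were available.
* The chi-square binning scheme and feature scaling are unstated in the
  source; quantile binning and training-fold standardization are this
  package's documented choices (both have config alternatives).
* Whether texture halves should apply to oriented subbands is unstated;
  applying them everywhere is a superset of any narrower reading.
* The inverse transform, complex-phase features, video/temporal
  features (lung sliding) and nonlinear classifiers are out of scope.
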