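---
title: "Optomic texture classification of fluorescence specimen images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optomic texture classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(optomics)
```

## The problem

Fluorescence-guided surgery images tumors through the differential uptake of
a molecularly targeted fluorescent agent (here, an EGFR-targeted agent in
head-and-neck squamous cell carcinoma specimens). The conventional reading
of such images is a global intensity threshold: brighter means tumor. In
practice the intensity histograms of tumor and normal tissue overlap
badly — normal mucosa and salivary gland express EGFR endogenously and
fluoresce brightly, while necrotic tumor cores fluoresce weakly — so
intensity alone misclassifies exactly those regions.

What does differ systematically is *spatial texture*: normal-tissue
fluorescence is homogeneous and spatially ordered, tumor fluorescence is
heterogeneous and disordered. This package implements an "optomics"
analysis that exploits that difference: radiomic-style texture features are
computed on small square patches of the standardized fluorescence image and
fed to a classifier, which is compared head-to-head against the intensity
threshold on the same specimens.

## Pre-processing

Each slice image passes through a fixed chain:

1. `subtractBackground()` — subtract a constant background level, clamping
   at zero (fluorescence is non-negative; the clamp is our convention).
2. `calibrate()` — divide by the intensity of a calibration target placed
   in the field of view, removing day-to-day instrument gain.
3. `rescaleRoiUnit()` — linear min–max rescaling computed from the ROI
   pixels only (union of tumor and normal ROIs) so all ROI pixels span
   [0, 1]; non-ROI pixels get the same map and are clipped. How non-ROI
   pixels should be treated is genuinely open; clipping keeps the image
   interpretable without affecting any ROI statistic.

The chain makes the output invariant to any positive rescaling of the raw
image (dose, exposure, gain), which is the property the downstream
comparison relies on: both methods see dose-free inputs.

## Patch sampling

Training patches are squares of odd side (1.8 mm ≈ 43 px at 0.042 mm/px)
drawn uniformly without replacement from "valid centers": pixels whose
window lies inside the image and has at least 90 % of its area inside a
single ROI. The containment rule thins patches near ROI boundaries, where
ground truth is least reliable. Testing patches are drawn over the whole
tissue surface; they receive an evaluation label only when one ROI covers
at least the same 90 % fraction, and remain "unlabeled" (but still scored)
otherwise, so probability maps can cover boundary tissue that accuracy
metrics cannot honestly judge.

Per-class patch counts default to an area-proportional density of
1.1 patches/mm² of ROI, which reproduces the order of magnitude of
per-specimen patch counts reported for real bread-loafed slices; a fixed
per-class count can be set instead (the reduced configurations do this).
Coordinates are 1-based (row, col), the idiomatic R convention; a patch of
side *s* centered at *c* spans rows *c − (s−1)/2 … c + (s−1)/2*.

## Features

Each patch yields 92 base features: 18 first-order intensity statistics
plus 74 texture features from five families — 23 GLCM (co-occurrence),
16 GLRLM (run length), 16 GLSZM (size zone), 14 GLDM (dependence) and
5 NGTDM (neighborhood tone difference) — following the IBSI nomenclature.
The same 92 are recomputed on each member of a 15-filter bank (4
stationary Haar wavelet sub-bands; 5 Laplacian-of-Gaussian scales at
σ = 0.25–1.25 mm; square, square root, logarithm, exponential, gradient
magnitude and discrete Laplacian), giving 92 × 16 = 1,472 features per
patch. Filter outputs are rescaled to the input patch's intensity range
before discretization so all images are quantized comparably.

Numerical conventions, chosen so every feature is finite on any patch:

* Discretization: fixed bin *count* (32) over the patch's own min–max
  range; half-open bins, last bin closed; a constant patch has one level.
* 0·log 0 = 0 throughout; skewness and kurtosis of a constant patch are 0.
* Constant-patch texture conventions: GLCM contrast 0, correlation 1,
  joint entropy 0, MCC 1; NGTDM coarseness capped at 10⁶.
* GLCM: distance 1, four 2-D angles, symmetric matrices, features averaged
  over angles (making them invariant to 90° rotations).
* GLDM: dependence of a pixel is 1 + the number of its 8-neighbours with
  level difference ≤ α (α = 0); counting the center keeps the
  small-dependence emphases defined for isolated pixels.
* GLSZM zones are 8-connected constant-level components.

Every texture family is verified against an independent brute-force
enumeration (explicit pair/run/zone loops) on small integer patches to
1e-10 in the test suite.

Features are Z-scored per feature before model fitting; test tables are
standardized with the *training* statistics, never their own.

## Feature selection and the classifier grid

Seven rankers are available: MRMR (greedy forward selection, difference
scheme — relevance minus mean redundancy, both as plug-in mutual
information on 8-bin equal-frequency discretized features) and six
univariate scores (Fisher score, contingency chi-square, Gini gain, mutual
information, |Spearman|, |Pearson|). Ties break lexicographically by
feature name so rankings are deterministic. MRMR's first pick provably
equals the mutual-information ranking's first pick.

Seven classifiers are wrapped with fixed settings: SVM (RBF kernel,
internal probability calibration), kNN (k = 5), decision tree, random
forest (100 trees), gradient boosting (50 rounds, depth 3), Gaussian naive
Bayes, and linear discriminant analysis. The classifier *type* is the
hyperparameter; internals are pinned and seeded.

Model selection runs specimen-level leave-one-out cross-validation on the
training set: each fold holds out all patches of one specimen, and Z-score
statistics and rankings are recomputed within the fold so nothing from the
held-out specimen leaks into selection (a property the tests assert by
corrupting held-out specimens). The default grid is 7 classifiers × 7
selectors × 20 feature counts (5–100 by 5) = 980 combinations. The winner
is chosen by a parsimony rule: among combinations whose mean CV accuracy is
within 1.5 standard deviations (of the best combination's fold accuracies)
of the maximum, take the fewest features, then the higher mean, then tag
order. The "1.5 SD" could also be read across combinations; we fixed the
fold-accuracy reading because it anchors the tolerance to the fold noise of
the best model.

## The thresholding baseline

`fitOcp()` sweeps every unique training ROI-pixel intensity, the midpoints
between consecutive unique intensities, and one value above the maximum,
classifying tumor at intensity ≥ t, and returns the lowest threshold
maximizing training accuracy (the optimum cutoff point). Evaluation is
pixel-level within ROIs: tumor pixels at/above the OCP are true positives;
normal pixels at/above it are false positives. The sweep is verified
against exhaustive enumeration on random instances.

## Evaluation and comparison

Both methods are scored per test specimen — optomics on labeled patches,
thresholding on ROI pixels — with accuracy, FPR = FP/(FP+TN) and
FNR = FN/(FN+TP), aggregated as unweighted means over specimens, and
compared with a paired two-sided t-test across specimens. Conventions:
all-zero paired differences give p = 1; zero variance with nonzero mean
reports p = 0 with an infinite t statistic.

## Probability maps

Patch probabilities are attached to patch center pixels. To reduce the
bias of crediting one window size, three models are trained at 1.8, 1.4
and 0.9 mm patch sides around the *same* centers and their probabilities
averaged per center (centers missing from a scale are averaged over the
available ones and flagged). The center values are interpolated over the
tissue support with a biharmonic spline: radial basis g(r) = r²(ln r − 1),
g(0) = 0, augmented with a constant term under a zero-sum weight
condition. The constant term is deliberate: the pure Green's-function
system does not reproduce constant fields, so symmetric data would not
interpolate to symmetric values (four corners valued {0,0,1,1} would give
0.16, not 0.5, at the midpoint). With the constant term the interpolant
still passes exactly through every node — the testable contract — and
behaves correctly on constants. Values are clipped to [0, 1]; the map is
defined only on tissue pixels.

## The synthetic cohort generator

No clinical images ship with the package; `generateSpecimen()` /
`generateCohort()` produce the study conditions the analysis assumes:

* **Normal tissue**: a Gaussian random field — white noise smoothed with a
  Gaussian kernel (correlation length 12 px) — mean 0.35, sd 0.12:
  "ordered" texture.
* **Tumor**: a sum of ~Poisson-many random elliptical blobs (scale 6 px,
  amplitude jitter) plus unsmoothed white noise (sd 0.10), total mean
  0.55, sd 0.15: brighter on average but heterogeneous and disordered, and
  overlapping the normal histogram by construction.
* **Mucosa band**: a bright (mean 0.65), low-variance (sd 0.05) band of
  normal tissue 8 px wide along the specimen edge — the false-positive
  trap for thresholding.
* **Necrotic core**: a dark (mean 0.20) region inside the tumor covering
  ~12 % of its area — the false-negative trap.
* **Dose groups**: three brightness scales (0.5 / 1.0 / 1.6) emulating
  inter-dose differences that pre-processing must remove.
* A constant calibration patch sits in the background corner; a global
  seed expands to per-specimen seeds so cohorts are bit-reproducible.

Default geometry (480 × 480 px at 0.042 mm/px; tissue ellipse ≈ 160 mm²,
tumor ≈ 30 mm², jittered per specimen) puts ROI areas and patch counts on
the scale reported for real bread-loafed slices. Where the generator had no
quantitative anchor (blob density, boundary-roughness harmonics, necrosis
noise), values were fixed once at what produces a visually and
statistically plausible regime and not revisited.

What the generator does *not* emulate: optical physics (scattering,
absorption, depth effects), camera noise, registration error between
histology and fluorescence, inter-patient biology, or any real EGFR
spatial statistics — the real texture statistics are unpublished. Passing
tests on this cohort therefore demonstrate that the pipeline recovers a
texture signal of the designed kind under intensity confounding; they do
not certify performance on clinical images.

## Problem sizes used by the tests and the acceptance script

The full design (area-proportional density → ~10⁴ training patches, 1,472
features, 980 combinations) is supported but slow; the shipped experiments
use `smokeConfig()`: the same 24-specimen cohort and 75/25 split, 30
patches per class per training specimen, 92 base features + 4 filters
(two wavelet sub-bands, finest LoG, gradient), and an SVM × MRMR × {10, 25}
grid. Four preregistered seeds drive the headline comparison in the test
suite; the acceptance script runs one seed end-to-end and reports both
methods' mean accuracy/FPR/FNR, the OCP, the LOOCV accuracy of the winning
combination and the paired-test p-value.

## Known limitations

* Feature values are not numerically identical to any specific external
  radiomics toolkit version (binning, aggregation and degenerate-case
  conventions differ between toolkits); the definitions above are fixed
  and oracle-tested instead.
* The MRMR variant (difference scheme, plug-in MI, 8 bins) is one of
  several reasonable choices; rankings can differ between variants.
* Specimen-level (not patient-level) partitioning mirrors the small-cohort
  design it reproduces; correlated slices from one patient can inflate
  apparent performance.
* Pixel-level accuracy of the probability maps is intentionally not scored.
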