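# optomics

Texture-feature ("optomic") classification of tumor versus normal tissue in
wide-field fluorescence images of bread-loafed surgical specimens, with a
head-to-head comparison against conventional fluorescence-intensity
thresholding, and multi-scale tumor-probability maps.

## Who this is for

Researchers in fluorescence-guided surgery and quantitative pathology who
want to test whether *spatial texture* of a molecularly targeted
fluorescence signal separates malignant from non-malignant tissue where raw
intensity cannot: normal mucosa expresses the target endogenously and
fluoresces brightly (false positives for a threshold), necrotic tumor cores
fluoresce weakly (false negatives), and the two intensity histograms
overlap. The package ships a synthetic specimen generator that reproduces
exactly this regime, so the whole analysis is runnable and testable without
clinical data.

## The method

Each standardized slice image (background-subtracted, calibrated, ROI
intensities rescaled to [0, 1]) is sampled into square patches (1.8 mm ≈
43 px; centers inside pathologist-style ROIs with a ≥90 % containment
rule). Every patch is described by 1,472 features: 92 base features — 18
first-order statistics plus 74 texture features from the GLCM, GLRLM,
GLSZM, GLDM and NGTDM families (IBSI nomenclature) — computed on the raw
patch and on each of 15 filtered versions (4 stationary wavelet sub-bands,
5 Laplacian-of-Gaussian scales, 6 intensity/derivative transforms).
Features are Z-scored with training statistics.

Model selection runs specimen-level leave-one-out cross-validation over a
grid of 7 classifiers × 7 feature-selection algorithms (MRMR and six
univariate scores) × 20 feature counts (5–100), choosing the fewest
features within 1.5 SD of the maximum mean validation accuracy. The
baseline is an optimum cutoff point (OCP): the intensity threshold t
maximizing training pixel accuracy for the rule "tumor if x ≥ t", found by
an exhaustive ROC sweep. Both methods are scored per test specimen
(accuracy, FPR = FP/(FP+TN), FNR = FN/(FN+TP)) and compared with a paired
two-sided t-test. Patch probabilities from models at three scales (1.8,
1.4, 0.9 mm) around shared centers are averaged and interpolated into a
pixel-level tumor-probability map with a biharmonic spline
(g(r) = r²(ln r − 1) radial basis plus a constant term).

## Worked example

```r
library(optomics)

res <- runDemo(smokeConfig(1))   # 24 synthetic specimens, ~2 min on 1 CPU

res$reportOptomics
#> EvalReport (optomics): 6 specimens
#>   mean accuracy 1.000, FPR 0.000, FNR 0.000
res$reportThresholding
#> EvalReport (thresholding): 6 specimens
#>   mean accuracy 0.806, FPR 0.007, FNR 0.903
res$ocpModel
#> ThresholdModel: OCP = 0.6398 (training accuracy 0.829)
res$model
#> OptomicsModel: SVM classifier, MRMR selection, 10 features, 1.8 mm patches
res$comparison[1, c("metric", "meanA", "meanB", "p")]
#>     metric meanA     meanB            p
#> 1 accuracy     1 0.8063936 1.168084e-05
```

Reading these numbers: on the 6 held-out synthetic specimens the texture
classifier is essentially perfect (the generator's tumor texture is
designed to be separable), while the best possible global intensity
threshold reaches only ~81 % pixel accuracy — it fits a high cutoff
(OCP ≈ 0.64 on the [0, 1] standardized scale) because normal pixels
dominate, and consequently misses most tumor pixels (FNR ≈ 0.90). The
paired test confirms the accuracy gap is consistent across specimens. The
`smokeConfig()` run uses 30 patches per class per training specimen, the
92 base features plus 4 filters, and an SVM × MRMR × {10, 25} grid; see
the methods vignette (`vignettes/optomics-methods.Rmd`) for the full
design and every numerical convention.

Probability maps for the test specimens:

```r
res <- runDemo(modifyList(smokeConfig(1), list(makeMaps = TRUE)))
str(res$maps[[1]]$map)   # matrix of tumor probabilities, NA off tissue
```

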