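Package: optomics
Title: Texture-Feature Classification of Tumor in Wide-Field Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for "optomic" analysis of wide-field fluorescence images of
    bread-loafed surgical specimens: radiomic-style texture feature extraction
    (first-order, GLCM, GLRLM, GLSZM, GLDM and NGTDM families over a bank of
    image filters) from square sub-image patches, feature ranking (minimum
    redundancy maximum relevance and six univariate criteria), specimen-level
    leave-one-out cross-validated model selection over a classifier grid, a
    fluorescence-intensity thresholding baseline with ROC optimal-cutoff
    fitting, multi-scale tumor-probability maps via biharmonic spline
    interpolation, and a synthetic specimen generator that reproduces the
    qualitative contrast regime of EGFR-targeted fluorescence imaging
    (overlapping intensity histograms, ordered normal vs. disordered tumor
    texture, bright mucosa bands and dark necrotic cores).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    MASS,
    class,
    rpart,
    randomForest,
    xgboost,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
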