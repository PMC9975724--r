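#' @import methods
#' @importFrom stats quantile sd var cor median rnorm runif rpois pt predict
#' @importFrom utils head write.csv read.csv
#' @useDynLib optomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Core data containers
# ---------------------------------------------------------------------------

#' SpecimenImage: one bread-loafed slice's grayscale fluorescence raster
#'
#' Holds a single-channel fluorescence image of one bread-loafed tissue slice
#' together with its acquisition metadata: the physical pixel size, the dose
#' group of the patient the slice came from, and the intensity measured on the
#' in-field calibration target (used by [calibrate()]).
#'
#' @slot pixels numeric matrix of non-negative intensities (row, col).
#' @slot pixelSizeMm physical pixel size in mm (default 0.042).
#' @slot specimenId character identifier, unique within a cohort.
#' @slot doseGroup integer dose-group label (1, 2 or 3).
#' @slot calibrationValue intensity of the calibration target in this image.
#' @slot isStandardized TRUE once the image has been background-subtracted,
#'   calibrated and ROI-rescaled to \[0,1\] (see [preprocessSpecimen()]).
#' @export
setClass("SpecimenImage",
  representation(
    pixels = "matrix",
    pixelSizeMm = "numeric",
    specimenId = "character",
    doseGroup = "integer",
    calibrationValue = "numeric",
    isStandardized = "logical"
  ),
  prototype(
    pixelSizeMm = 0.042,
    specimenId = "specimen",
    doseGroup = 1L,
    calibrationValue = 1,
    isStandardized = FALSE
  )
)

setValidity("SpecimenImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels)) msg <- c(msg, "pixels must be numeric")
  if (length(object@pixelSizeMm) != 1L || object@pixelSizeMm <= 0)
    msg <- c(msg, "pixelSizeMm must be a single positive number")
  if (!object@doseGroup %in% 1:3) msg <- c(msg, "doseGroup must be 1, 2 or 3")
  if (length(object@calibrationValue) != 1L || object@calibrationValue <= 0)
    msg <- c(msg, "calibrationValue must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a SpecimenImage
#'
#' @param pixels numeric matrix of intensities.
#' @param pixelSizeMm pixel size in mm.
#' @param specimenId identifier string.
#' @param doseGroup dose group (1, 2 or 3).
#' @param calibrationValue calibration-target intensity.
#' @param isStandardized whether the image is already standardized.
#' @return A [SpecimenImage-class] object.
#' @export
SpecimenImage <- function(pixels, pixelSizeMm = 0.042, specimenId = "specimen",
                          doseGroup = 1L, calibrationValue = 1,
                          isStandardized = FALSE) {
  new("SpecimenImage", pixels = pixels, pixelSizeMm = pixelSizeMm,
      specimenId = specimenId, doseGroup = as.integer(doseGroup),
      calibrationValue = calibrationValue, isStandardized = isStandardized)
}

#' LabelMask: per-pixel ground-truth labels for a specimen image
#'
#' Integer labels co-registered to a [SpecimenImage-class]:
#' 0 = background, 1 = normal-tissue ROI, 2 = tumor ROI.
#'
#' @slot labels integer matrix with values in \{0, 1, 2\}.
#' @export
setClass("LabelMask", representation(labels = "matrix"))

setValidity("LabelMask", function(object) {
  v <- unique(as.vector(object@labels))
  if (!all(v %in% 0:2)) return("labels must take values in {0, 1, 2}")
  TRUE
})

#' Construct a LabelMask
#' @param labels integer matrix with values in \{0,1,2\}.
#' @return A [LabelMask-class] object.
#' @export
LabelMask <- function(labels) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels)
}

#' SceneSpec: parameters of one synthetic bread-loaf specimen
#'
#' Describes the forward model used by [generateSpecimen()]: the image grid,
#' specimen and tumor geometry, the two texture models (smooth correlated
#' normal field vs. blob-plus-noise tumor field), the bright mucosa band, the
#' dark necrotic core, dose scaling and the calibration patch.
#'
#' @slot imageHeightPx,imageWidthPx image size in pixels.
#' @slot pixelSizeMm pixel size (mm).
#' @slot doseGroup dose group 1..3.
#' @slot doseScale multiplicative brightness factor for the group.
#' @slot tissueGeometry list(centerFrac, radiiPx, roughness, nHarmonics).
#' @slot tumorGeometry list(centerOffsetFrac, radiiPx, roughness, nHarmonics).
#' @slot mucosaBandWidthPx width of the bright band at the specimen edge (px).
#' @slot necrosisFraction area fraction of the tumor occupied by the dark core.
#' @slot normalTexture list(mean, sd, correlationLengthPx).
#' @slot tumorTexture list(mean, sd, blobScalePx, disorderSd).
#' @slot mucosaTexture list(mean, sd).
#' @slot necrosisMean mean intensity of the necrotic core.
#' @slot backgroundLevel constant background intensity.
#' @slot calibrationTargetValue intensity of the calibration patch (pre-dose).
#' @slot seed integer RNG seed; same spec implies bit-identical output.
#' @export
setClass("SceneSpec",
  representation(
    imageHeightPx = "integer", imageWidthPx = "integer",
    pixelSizeMm = "numeric", doseGroup = "integer", doseScale = "numeric",
    tissueGeometry = "list", tumorGeometry = "list",
    mucosaBandWidthPx = "integer", necrosisFraction = "numeric",
    normalTexture = "list", tumorTexture = "list", mucosaTexture = "list",
    necrosisMean = "numeric", backgroundLevel = "numeric",
    calibrationTargetValue = "numeric", seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@imageHeightPx < 32L || object@imageWidthPx < 32L)
    msg <- c(msg, "image must be at least 32 x 32 pixels")
  if (object@pixelSizeMm <= 0) msg <- c(msg, "pixelSizeMm must be positive")
  if (!object@doseGroup %in% 1:3) msg <- c(msg, "doseGroup must be in 1..3")
  if (object@doseScale <= 0) msg <- c(msg, "doseScale must be positive")
  if (object@necrosisFraction < 0 || object@necrosisFraction > 1)
    msg <- c(msg, "necrosisFraction must be in [0,1]")
  if (object@mucosaBandWidthPx < 0L)
    msg <- c(msg, "mucosaBandWidthPx must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpecimen: generated image + mask + generating parameters
#'
#' @slot image the [SpecimenImage-class].
#' @slot mask the co-registered [LabelMask-class].
#' @slot spec the [SceneSpec-class] that generated the pair.
#' @export
setClass("SyntheticSpecimen",
  representation(image = "SpecimenImage", mask = "LabelMask",
                 spec = "SceneSpec"))

#' PatchSpec: patch geometry and sampling parameters
#'
#' @slot sidePx odd patch side length in pixels.
#' @slot sideMm patch side length in mm.
#' @slot minInsideFraction minimum fraction of patch pixels required to carry
#'   the ROI label (containment rule, default 0.9).
#' @slot nPerClassTarget either a fixed per-class patch count per specimen, or
#'   NA to use `densityPerMm2`.
#' @slot densityPerMm2 sampling density (patches per mm^2 of ROI area).
#' @slot seed RNG seed for center sampling.
#' @export
setClass("PatchSpec",
  representation(sidePx = "integer", sideMm = "numeric",
                 minInsideFraction = "numeric", nPerClassTarget = "numeric",
                 densityPerMm2 = "numeric", seed = "integer"))

setValidity("PatchSpec", function(object) {
  msg <- character()
  if (object@sidePx < 3L || object@sidePx %% 2L == 0L)
    msg <- c(msg, "sidePx must be an odd integer >= 3")
  if (object@minInsideFraction <= 0 || object@minInsideFraction > 1)
    msg <- c(msg, "minInsideFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' PatchSet: a stack of equally-sized square patches with provenance
#'
#' Pixel data are stored as a 3-D array (side, side, n); per-patch provenance
#' (specimen, center, scale, label) is a data.frame accessible via
#' [patchInfo()].
#'
#' @slot pixels numeric array side x side x n.
#' @slot info data.frame with columns specimenId, centerRow, centerCol,
#'   scaleMm, label (one of "malignant", "non_malignant", "unlabeled").
#' @slot pixelSizeMm pixel size in mm.
#' @export
setClass("PatchSet",
  representation(pixels = "array", info = "data.frame",
                 pixelSizeMm = "numeric"))

setValidity("PatchSet", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L) return("pixels must be a 3-D array")
  if (d[1] != d[2]) return("patches must be square")
  if (d[3] != nrow(object@info)) return("info rows must match patch count")
  need <- c("specimenId", "centerRow", "centerCol", "scaleMm", "label")
  if (!all(need %in% names(object@info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (!all(object@info$label %in% c("malignant", "non_malignant", "unlabeled")))
    return("labels must be malignant / non_malignant / unlabeled")
  TRUE
})

# ---------------------------------------------------------------------------
# Models and reports
# ---------------------------------------------------------------------------

#' ThresholdModel: fluorescence-intensity thresholding baseline
#'
#' A pixel is classified malignant when its standardized intensity is greater
#' than or equal to the optimum cutoff point (OCP); see [fitOcp()].
#'
#' @slot ocp the optimum cutoff point on the standardized \[0,1\] scale.
#' @slot trainAccuracy pixel-level training accuracy achieved at the OCP.
#' @export
setClass("ThresholdModel",
  representation(ocp = "numeric", trainAccuracy = "numeric"))

#' OptomicsModel: a trained patch-level texture classifier
#'
#' @slot classifier classifier tag (one of RF, kNN, DT, SVM, BST, BY, DA).
#' @slot selector feature-selection tag (MRMR, FSCR, CHSQ, GINI, MIM, SRCC,
#'   PRCC).
#' @slot features character vector of selected feature names, in rank order.
#' @slot centerStats data.frame(feature, mu, sd) Z-score statistics computed
#'   on the training table; applied to any table scored by the model.
#' @slot fit fitted backend object (opaque).
#' @slot scaleMm patch scale the model was trained at.
#' @export
setClass("OptomicsModel",
  representation(classifier = "character", selector = "character",
                 features = "character", centerStats = "data.frame",
                 fit = "ANY", scaleMm = "numeric"))

#' EvalReport: per-specimen and aggregate classification metrics
#'
#' @slot method "optomics" or "thresholding".
#' @slot perSpecimen data.frame with one row per evaluated specimen:
#'   specimenId, n, tp, fn, fp, tn, accuracy, fpr, fnr.
#' @slot aggregate named numeric: mean accuracy, fpr, fnr over specimens.
#' @export
setClass("EvalReport",
  representation(method = "character", perSpecimen = "data.frame",
                 aggregate = "numeric"))

# ---------------------------------------------------------------------------
# Accessors and show methods
# ---------------------------------------------------------------------------

#' Extract the pixel matrix of an image-like object
#' @param x a SpecimenImage, SyntheticSpecimen or ProbabilityMap.
#' @return numeric matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "SpecimenImage", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "SyntheticSpecimen", function(x) x@image@pixels)

#' Extract the integer label matrix of a mask-like object
#' @param x a LabelMask or SyntheticSpecimen.
#' @return integer matrix with values in \{0,1,2\}.
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @rdname maskLabels
#' @export
setMethod("maskLabels", "LabelMask", function(x) x@labels)

#' @rdname maskLabels
#' @export
setMethod("maskLabels", "SyntheticSpecimen", function(x) x@mask@labels)

#' Specimen identifier
#' @param x a SpecimenImage or SyntheticSpecimen.
#' @return character scalar.
#' @export
setGeneric("specimenId", function(x) standardGeneric("specimenId"))

#' @rdname specimenId
#' @export
setMethod("specimenId", "SpecimenImage", function(x) x@specimenId)

#' @rdname specimenId
#' @export
setMethod("specimenId", "SyntheticSpecimen", function(x) x@image@specimenId)

#' Dose group of a specimen
#' @param x a SpecimenImage or SyntheticSpecimen.
#' @return integer in 1..3.
#' @export
setGeneric("doseGroup", function(x) standardGeneric("doseGroup"))

#' @rdname doseGroup
#' @export
setMethod("doseGroup", "SpecimenImage", function(x) x@doseGroup)

#' @rdname doseGroup
#' @export
setMethod("doseGroup", "SyntheticSpecimen", function(x) x@image@doseGroup)

#' Is an image standardized to the unit ROI intensity range?
#' @param x a SpecimenImage.
#' @return logical scalar.
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))

#' @rdname isStandardized
#' @export
setMethod("isStandardized", "SpecimenImage", function(x) x@isStandardized)

#' Patch provenance table
#' @param x a PatchSet.
#' @return data.frame with one row per patch.
#' @export
setGeneric("patchInfo", function(x) standardGeneric("patchInfo"))

#' @rdname patchInfo
#' @export
setMethod("patchInfo", "PatchSet", function(x) x@info)

#' Number of patches in a PatchSet
#' @param x a PatchSet.
#' @export
setMethod("length", "PatchSet", function(x) dim(x@pixels)[3])

#' Extract one patch's pixel matrix
#' @param x a PatchSet.
#' @param i patch index.
#' @param j unused.
#' @param ... unused.
#' @export
setMethod("[[", "PatchSet", function(x, i, j, ...) x@pixels[, , i])

setMethod("show", "SpecimenImage", function(object) {
  cat(sprintf(
    "SpecimenImage '%s' (%d x %d px, %.3f mm/px, dose group %d, %s)\n",
    object@specimenId, nrow(object@pixels), ncol(object@pixels),
    object@pixelSizeMm, object@doseGroup,
    if (object@isStandardized) "standardized" else "raw"))
})

setMethod("show", "SyntheticSpecimen", function(object) {
  tab <- tabulate(as.vector(object@mask@labels) + 1L, 3L)
  cat(sprintf(
    "SyntheticSpecimen '%s': %d x %d px; background/normal/tumor pixels %d/%d/%d\n",
    specimenId(object), nrow(object@image@pixels), ncol(object@image@pixels),
    tab[1], tab[2], tab[3]))
})

setMethod("show", "PatchSet", function(object) {
  tab <- table(object@info$label)
  cat(sprintf("PatchSet: %d patches of %d x %d px (%.2f mm side)\n",
              length(object), dim(object@pixels)[1], dim(object@pixels)[2],
              dim(object@pixels)[1] * object@pixelSizeMm))
  print(tab)
})

setMethod("show", "ThresholdModel", function(object) {
  cat(sprintf("ThresholdModel: OCP = %.4f (training accuracy %.3f)\n",
              object@ocp, object@trainAccuracy))
})

setMethod("show", "OptomicsModel", function(object) {
  cat(sprintf(
    "OptomicsModel: %s classifier, %s selection, %d features, %.1f mm patches\n",
    object@classifier, object@selector, length(object@features),
    object@scaleMm))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (%s): %d specimens\n", object@method,
              nrow(object@perSpecimen)))
  cat(sprintf("  mean accuracy %.3f, FPR %.3f, FNR %.3f\n",
              object@aggregate[["accuracy"]], object@aggregate[["fpr"]],
              object@aggregate[["fnr"]]))
})
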