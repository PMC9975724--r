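# Image pre-processing: background subtraction, calibration normalisation and
# per-slice rescaling of ROI intensities to [0,1]. The fixed composition
# order (subtract -> calibrate -> rescale) removes instrument offsets,
# day-to-day instrument variation, and dose-driven inter-slice brightness
# bias: multiplying a raw image and its calibration value by any positive
# constant leaves the standardized output unchanged.

#' Subtract a constant background level from a specimen image
#'
#' Negative results are clamped to zero (fluorescence is non-negative).
#'
#' @param image a [SpecimenImage-class].
#' @param backgroundLevel non-negative background intensity.
#' @return A [SpecimenImage-class] with pixels `max(pixels - background, 0)`.
#' @export
subtractBackground <- function(image, backgroundLevel) {
  stopifnot(is(image, "SpecimenImage"), backgroundLevel >= 0)
  image@pixels <- pmax(image@pixels - backgroundLevel, 0)
  image
}

#' Normalise a specimen image to its fluorescence calibration target
#'
#' Divides all pixels by the calibration-target intensity, removing
#' instrument- and session-specific gain.
#'
#' @param image a [SpecimenImage-class].
#' @param calibrationValue positive calibration intensity; defaults to the
#'   value recorded in the image metadata.
#' @return A calibrated [SpecimenImage-class].
#' @export
calibrate <- function(image, calibrationValue = image@calibrationValue) {
  stopifnot(is(image, "SpecimenImage"))
  if (calibrationValue <= 0) stop("calibrationValue must be positive")
  image@pixels <- image@pixels / calibrationValue
  image@calibrationValue <- 1
  image
}

#' Rescale a specimen image so all ROI pixels span \[0,1\]
#'
#' The linear min-max map is computed from ROI pixels only (mask labels 1 and
#' 2) and applied to every pixel; non-ROI pixels falling outside \[0,1\] are
#' clipped. A constant ROI (max = min) yields all-zero ROI pixels with a
#' warning.
#'
#' @param image a [SpecimenImage-class].
#' @param mask the co-registered [LabelMask-class].
#' @return A standardized [SpecimenImage-class] (`isStandardized = TRUE`).
#' @export
rescaleRoiUnit <- function(image, mask) {
  stopifnot(is(image, "SpecimenImage"), is(mask, "LabelMask"))
  roi <- mask@labels >= 1L
  if (!any(roi)) stop("mask contains no ROI pixels")
  v <- image@pixels[roi]
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    warning("constant ROI intensities; ROI pixels set to 0")
    image@pixels[] <- 0
  } else {
    image@pixels <- pmin(pmax((image@pixels - lo) / (hi - lo), 0), 1)
  }
  image@isStandardized <- TRUE
  image
}

#' Run the full pre-processing chain on one specimen
#'
#' Applies [subtractBackground()], [calibrate()] (using the image's recorded
#' calibration value) and [rescaleRoiUnit()] in that order.
#'
#' @param specimen a [SyntheticSpecimen-class], or a [SpecimenImage-class]
#'   with `mask` supplied.
#' @param backgroundLevel background intensity to subtract; for a synthetic
#'   specimen defaults to the generating spec's (dose-scaled) background.
#' @param mask a [LabelMask-class] (required when `specimen` is a bare
#'   image).
#' @return A standardized [SpecimenImage-class].
#' @export
preprocessSpecimen <- function(specimen, backgroundLevel = NULL, mask = NULL) {
  if (is(specimen, "SyntheticSpecimen")) {
    if (is.null(backgroundLevel))
      backgroundLevel <- specimen@spec@backgroundLevel * specimen@spec@doseScale
    mask <- specimen@mask
    image <- specimen@image
  } else {
    image <- specimen
    if (is.null(mask)) stop("mask required for a bare SpecimenImage")
    if (is.null(backgroundLevel)) backgroundLevel <- 0
  }
  img <- subtractBackground(image, backgroundLevel)
  img <- calibrate(img)
  rescaleRoiUnit(img, mask)
}
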