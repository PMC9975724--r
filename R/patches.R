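# Square sub-image patch sampling. Training patches are drawn from
# pathologist-style ROIs under a containment rule (at least 90% of the patch
# area inside the ROI); testing patches are drawn over the whole tissue
# surface and only receive an evaluation label when one ROI covers at least
# the containment fraction of the patch.

#' Convert a physical patch side length to an odd pixel count
#'
#' Rounds to the nearest odd integer so the patch has an unambiguous center
#' pixel; 1.8 mm at 0.042 mm/px maps to 43 px, 1.4 mm to 33 px, 0.9 mm to
#' 21 px.
#'
#' @param sideMm patch side in mm.
#' @param pixelSizeMm pixel size in mm.
#' @return odd integer pixel count.
#' @export
sideMmToPx <- function(sideMm, pixelSizeMm = 0.042) {
  s <- round(sideMm / pixelSizeMm)
  s <- ifelse(s %% 2 == 0,
              ifelse(sideMm / pixelSizeMm >= s, s + 1, s - 1), s)
  as.integer(pmax(s, 3))
}

#' Construct a PatchSpec
#'
#' @param sideMm patch side length in mm (default 1.8).
#' @param pixelSizeMm pixel size used to derive `sidePx` (default 0.042).
#' @param sidePx odd patch side in pixels; derived from `sideMm` by default.
#' @param minInsideFraction containment fraction (default 0.9).
#' @param nPerClassTarget fixed per-class patch count per specimen; `NA`
#'   (default) means use `densityPerMm2`.
#' @param densityPerMm2 sampling density in patches per mm^2 of ROI area
#'   (default 1.1, calibrated so a 24-slice cohort with realistic ROI areas
#'   yields on the order of 10^4 training patches).
#' @param seed RNG seed for center sampling.
#' @return A [PatchSpec-class].
#' @export
patchSpec <- function(sideMm = 1.8, pixelSizeMm = 0.042,
                      sidePx = sideMmToPx(sideMm, pixelSizeMm),
                      minInsideFraction = 0.9, nPerClassTarget = NA_real_,
                      densityPerMm2 = 1.1, seed = 1L) {
  new("PatchSpec", sidePx = as.integer(sidePx), sideMm = sideMm,
      minInsideFraction = minInsideFraction,
      nPerClassTarget = as.numeric(nPerClassTarget),
      densityPerMm2 = densityPerMm2, seed = as.integer(seed))
}

# 2-D summed-area table with a zero first row/col for O(1) window sums.
integralImage <- function(x) {
  s <- apply(apply(x, 2, cumsum), 1, cumsum)
  rbind(0, cbind(0, t(s)))
}

windowSums <- function(ii, side, nr, nc) {
  h <- (side - 1L) %/% 2L
  rows <- (h + 1L):(nr - h)
  cols <- (h + 1L):(nc - h)
  r1 <- rows - h; r2 <- rows + h
  c1 <- cols - h; c2 <- cols + h
  ii[r2 + 1, c2 + 1, drop = FALSE] - ii[r1, c2 + 1, drop = FALSE] -
    ii[r2 + 1, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
}

#' Enumerate valid patch centers for one ROI label
#'
#' A center is valid when the square window of `spec@sidePx` centered on it
#' lies fully inside the image and at least `minInsideFraction` of its pixels
#' carry `roiLabel`. ROI-edge centers are excluded by the rule, giving the
#' characteristic sparse patch distribution near ROI boundaries.
#'
#' @param mask a [LabelMask-class].
#' @param roiLabel ROI label (1 = normal, 2 = tumor).
#' @param spec a [PatchSpec-class].
#' @return two-column matrix (row, col) of valid centers (possibly 0 rows).
#' @export
validCenters <- function(mask, roiLabel, spec) {
  stopifnot(is(mask, "LabelMask"), roiLabel %in% 1:2, is(spec, "PatchSpec"))
  lab <- mask@labels
  nr <- nrow(lab); nc <- ncol(lab)
  side <- spec@sidePx
  if (side > nr || side > nc)
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("row", "col"))))
  ii <- integralImage(lab == roiLabel)
  frac <- windowSums(ii, side, nr, nc) / side^2
  ok <- which(frac >= spec@minInsideFraction - 1e-12, arr.ind = TRUE)
  h <- (side - 1L) %/% 2L
  out <- cbind(row = ok[, 1] + h, col = ok[, 2] + h)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# Extract side x side windows centered at the given (row, col) centers.
extractWindows <- function(pixelsMat, centers, side) {
  h <- (side - 1L) %/% 2L
  n <- nrow(centers)
  out <- array(0, c(side, side, n))
  for (i in seq_len(n)) {
    r <- centers[i, 1]; c <- centers[i, 2]
    out[, , i] <- pixelsMat[(r - h):(r + h), (c - h):(c + h)]
  }
  out
}

patchLabelName <- c("non_malignant", "malignant")

targetCount <- function(spec, nAvailable, areaMm2) {
  if (!is.na(spec@nPerClassTarget)) n <- round(spec@nPerClassTarget)
  else n <- round(spec@densityPerMm2 * areaMm2)
  max(min(n, nAvailable), 0L)
}

#' Sample labeled training patches from one standardized specimen
#'
#' Centers are drawn uniformly without replacement from the valid centers of
#' each ROI label ([validCenters()]); the patch label is the ROI label of its
#' center. The per-class count follows `spec@nPerClassTarget` if set, else
#' the area-proportional density `spec@densityPerMm2`; when more patches are
#' requested than centers exist, all available centers are used with a
#' warning.
#'
#' @param image a standardized [SpecimenImage-class].
#' @param mask the co-registered [LabelMask-class].
#' @param spec a [PatchSpec-class].
#' @return A [PatchSet-class] with labels malignant / non_malignant.
#' @export
sampleTrainingPatches <- function(image, mask, spec) {
  stopifnot(is(image, "SpecimenImage"))
  if (!image@isStandardized)
    stop("patches must be sampled from a standardized image")
  set.seed(spec@seed + hashId(image@specimenId))
  allCenters <- list(); allLabels <- character()
  for (roiLabel in c(2L, 1L)) {
    ctr <- validCenters(mask, roiLabel, spec)
    areaMm2 <- sum(mask@labels == roiLabel) * image@pixelSizeMm^2
    n <- targetCount(spec, nrow(ctr), areaMm2)
    if (!is.na(spec@nPerClassTarget) && spec@nPerClassTarget > nrow(ctr))
      warning(sprintf("only %d valid centers for label %d (requested %d)",
                      nrow(ctr), roiLabel, round(spec@nPerClassTarget)))
    if (n > 0) {
      pick <- sort(sample.int(nrow(ctr), n))
      allCenters[[length(allCenters) + 1L]] <- ctr[pick, , drop = FALSE]
      allLabels <- c(allLabels, rep(patchLabelName[roiLabel], n))
    }
  }
  centers <- do.call(rbind, c(allCenters,
                              list(matrix(integer(), 0, 2))))
  buildPatchSet(image, centers, allLabels, spec)
}

#' Sample testing patches over the entire tissue surface
#'
#' Centers are drawn uniformly without replacement from all tissue pixels
#' (mask label != 0) whose window fits inside the image. Each patch receives
#' an evaluation label only when at least `minInsideFraction` of its pixels
#' share a single ROI label; patches straddling boundaries are "unlabeled"
#' but still receive model predictions (for probability maps).
#'
#' @param image a standardized [SpecimenImage-class].
#' @param mask the co-registered [LabelMask-class].
#' @param spec a [PatchSpec-class].
#' @param centers optional fixed (row, col) matrix of centers (used for
#'   co-located multi-scale sampling); when supplied no random draw occurs.
#' @return A [PatchSet-class].
#' @export
sampleTestingPatches <- function(image, mask, spec, centers = NULL) {
  stopifnot(is(image, "SpecimenImage"))
  if (!image@isStandardized)
    stop("patches must be sampled from a standardized image")
  lab <- mask@labels
  nr <- nrow(lab); nc <- ncol(lab)
  side <- spec@sidePx
  h <- (side - 1L) %/% 2L
  if (is.null(centers)) {
    set.seed(spec@seed + hashId(image@specimenId) + 7L)
    tissue <- which(lab != 0L, arr.ind = TRUE)
    inb <- tissue[, 1] > h & tissue[, 1] <= nr - h &
      tissue[, 2] > h & tissue[, 2] <= nc - h
    tissue <- tissue[inb, , drop = FALSE]
    if (nrow(tissue) == 0)
      return(buildPatchSet(image, matrix(integer(), 0, 2), character(), spec))
    areaMm2 <- nrow(tissue) * image@pixelSizeMm^2
    n <- targetCount(spec, nrow(tissue), areaMm2)
    pick <- sort(sample.int(nrow(tissue), n))
    centers <- tissue[pick, , drop = FALSE]
  }
  if (side > nr || side > nc || nrow(centers) == 0)
    return(buildPatchSet(image, matrix(integer(), 0, 2), character(), spec))
  iiT <- integralImage(lab == 2L)
  iiN <- integralImage(lab == 1L)
  boxSum <- function(ii, r, c)
    ii[r + h + 1, c + h + 1] - ii[r - h, c + h + 1] -
      ii[r + h + 1, c - h] + ii[r - h, c - h]
  labels <- character(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    r <- centers[i, 1]; c <- centers[i, 2]
    fT <- boxSum(iiT, r, c) / side^2
    fN <- boxSum(iiN, r, c) / side^2
    labels[i] <- if (fT >= spec@minInsideFraction - 1e-12) "malignant"
    else if (fN >= spec@minInsideFraction - 1e-12) "non_malignant"
    else "unlabeled"
  }
  buildPatchSet(image, centers, labels, spec)
}

buildPatchSet <- function(image, centers, labels, spec) {
  n <- nrow(centers)
  px <- if (n > 0) extractWindows(image@pixels, centers, spec@sidePx)
  else array(0, c(spec@sidePx, spec@sidePx, 0))
  info <- data.frame(
    specimenId = rep(image@specimenId, n),
    centerRow = as.integer(centers[, 1]),
    centerCol = as.integer(centers[, 2]),
    scaleMm = rep(spec@sidePx * image@pixelSizeMm, n),
    label = if (n) labels else character(),
    stringsAsFactors = FALSE)
  new("PatchSet", pixels = px, info = info, pixelSizeMm = image@pixelSizeMm)
}

# Small deterministic hash of a specimen id, used to decorrelate per-specimen
# sampling streams under one PatchSpec seed.
hashId <- function(id) {
  as.integer(sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) %% 99991L)
}

#' Combine PatchSets (same side length) into one
#' @param ... PatchSet objects.
#' @return A [PatchSet-class].
#' @export
combinePatchSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "PatchSet"))
    sets <- sets[[1]]
  sets <- Filter(function(s) length(s) > 0, sets)
  if (!length(sets)) stop("no non-empty PatchSets to combine")
  side <- dim(sets[[1]]@pixels)[1]
  stopifnot(all(vapply(sets, function(s) dim(s@pixels)[1], 0) == side))
  px <- array(unlist(lapply(sets, function(s) s@pixels)),
              c(side, side, sum(vapply(sets, length, 0L))))
  info <- do.call(rbind, lapply(sets, patchInfo))
  rownames(info) <- NULL
  new("PatchSet", pixels = px, info = info,
      pixelSizeMm = sets[[1]]@pixelSizeMm)
}
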