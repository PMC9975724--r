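# Pixel-level tumor-probability maps. Patch-level model probabilities are
# attached to patch center pixels, optionally averaged across the three
# patch scales (1.8, 1.4, 0.9 mm windows sharing one center set), and
# interpolated over the tissue support with a biharmonic spline (2-D
# thin-membrane Green's function radial basis).

#' Attach model probabilities to patch centers
#'
#' @param model an [OptomicsModel-class]; its training scale must match the
#'   patches' scale.
#' @param table feature table of the patches to score.
#' @return data.frame(specimenId, centerRow, centerCol, prob).
#' @export
patchProbabilities <- function(model, table) {
  info <- as.data.frame(SummarizedExperiment::colData(table))
  if (!isTRUE(all.equal(model@scaleMm, info$scaleMm[1], tolerance = 1e-6)))
    stop(sprintf("model scale (%.2f mm) does not match patch scale (%.2f mm)",
                 model@scaleMm, info$scaleMm[1]))
  p <- modelProbabilities(model, table)
  if (any(p < 0 | p > 1)) {
    warning("probabilities outside [0,1] clipped")
    p <- pmin(pmax(p, 0), 1)
  }
  data.frame(specimenId = info$specimenId, centerRow = info$centerRow,
             centerCol = info$centerCol, prob = p,
             stringsAsFactors = FALSE)
}

#' Average per-scale center probabilities
#'
#' Arithmetic mean of the probabilities predicted at each center by the
#' models of the different patch scales. Centers present in only some
#' scales are averaged over the available scales and flagged.
#'
#' @param perScale list of data.frames from [patchProbabilities()], one per
#'   scale, sharing the (centerRow, centerCol) center set.
#' @return data.frame(centerRow, centerCol, prob, nScales, partial).
#' @export
multiscaleAverage <- function(perScale) {
  stopifnot(length(perScale) >= 1L)
  all <- do.call(rbind, lapply(perScale, function(d)
    d[, c("centerRow", "centerCol", "prob")]))
  key <- interaction(all$centerRow, all$centerCol, drop = TRUE)
  agg <- data.frame(
    centerRow = tapply(all$centerRow, key, `[`, 1),
    centerCol = tapply(all$centerCol, key, `[`, 1),
    prob = as.numeric(tapply(all$prob, key, mean)),
    nScales = as.integer(tapply(all$prob, key, length)))
  agg$partial <- agg$nScales < length(perScale)
  if (any(agg$partial))
    warning(sum(agg$partial),
            " centers missing from some scales; averaged over available")
  rownames(agg) <- NULL
  agg[order(agg$centerRow, agg$centerCol), ]
}

# Biharmonic (thin-membrane) Green's function with g(0) = 0.
biharmonicGreen <- function(r) {
  out <- r
  out[] <- 0
  pos <- r > 0
  out[pos] <- r[pos]^2 * (log(r[pos]) - 1)
  out
}

#' Biharmonic spline interpolation of center probabilities over tissue
#'
#' Exact scattered-data interpolation using the 2-D biharmonic Green's
#' function `g(r) = r^2 (ln r - 1)` (g(0) = 0) as radial basis, augmented
#' with a constant term under the side condition that the basis weights sum
#' to zero: the weights solve the linear system passing the surface through
#' every data point, and the constant term makes the interpolant reproduce
#' constant fields (so symmetric data interpolate to symmetric values).
#' The surface is evaluated on all tissue pixels and clipped to \[0,1\].
#' Duplicate centers are deduplicated by averaging with a warning; a single
#' center yields a constant map.
#'
#' @param centers data.frame with columns centerRow, centerCol, prob.
#' @param tissueMask logical matrix marking tissue pixels (or a
#'   [LabelMask-class], in which case labels != 0 define tissue).
#' @param clip clip interpolated values to \[0,1\] (default TRUE).
#' @return numeric matrix of the mask's size; NA outside the tissue.
#' @export
biharmonicInterpolate <- function(centers, tissueMask, clip = TRUE) {
  if (is(tissueMask, "LabelMask")) tissueMask <- tissueMask@labels != 0L
  stopifnot(nrow(centers) >= 1L)
  key <- paste(centers$centerRow, centers$centerCol)
  if (anyDuplicated(key)) {
    warning("duplicate centers averaged")
    centers <- data.frame(
      centerRow = tapply(centers$centerRow, key, `[`, 1),
      centerCol = tapply(centers$centerCol, key, `[`, 1),
      prob = as.numeric(tapply(centers$prob, key, mean)))
  }
  n <- nrow(centers)
  out <- matrix(NA_real_, nrow(tissueMask), ncol(tissueMask))
  pix <- which(tissueMask, arr.ind = TRUE)
  if (nrow(pix) == 0) return(out)
  if (n == 1L) {
    out[tissueMask] <- if (clip) min(max(centers$prob, 0), 1)
    else centers$prob
    return(out)
  }
  P <- cbind(centers$centerRow, centers$centerCol)
  D <- as.matrix(stats::dist(P))
  # Green's-function system augmented with a constant term (weights sum to
  # zero), so the interpolant reproduces constants and symmetric
  # configurations interpolate to their symmetric value.
  A <- rbind(cbind(biharmonicGreen(D), 1), c(rep(1, n), 0))
  sol <- solve(A, c(centers$prob, 0))
  w <- sol[seq_len(n)]
  const <- sol[n + 1L]
  vals <- numeric(nrow(pix))
  chunk <- 20000L
  for (start in seq(1L, nrow(pix), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(pix))
    dr <- outer(pix[idx, 1], P[, 1], "-")
    dc <- outer(pix[idx, 2], P[, 2], "-")
    G <- biharmonicGreen(sqrt(dr * dr + dc * dc))
    vals[idx] <- G %*% w + const
  }
  if (clip) vals <- pmin(pmax(vals, 0), 1)
  out[pix] <- vals
  out
}

#' Build a multi-scale tumor-probability map for one test specimen
#'
#' Samples co-located testing patches at each scale, scores them with the
#' matching per-scale model, averages the per-center probabilities and
#' interpolates over the tissue support.
#'
#' @param models list of [OptomicsModel-class], one per scale.
#' @param image standardized [SpecimenImage-class].
#' @param mask co-registered [LabelMask-class].
#' @param scalesMm patch side lengths in mm (default `c(1.8, 1.4, 0.9)`).
#' @param patchSpecTemplate [PatchSpec-class] template providing the
#'   containment fraction, density/count and seed; the side is set per
#'   scale. Centers are drawn once, valid for the largest window.
#' @param config [featureConfig()] for feature extraction.
#' @return list(map, centers) where `map` is the interpolated probability
#'   matrix (NA off tissue).
#' @export
probabilityMap <- function(models, image, mask,
                           scalesMm = c(1.8, 1.4, 0.9),
                           patchSpecTemplate = patchSpec(),
                           config = featureConfig(
                             pixelSizeMm = image@pixelSizeMm)) {
  stopifnot(length(models) == length(scalesMm))
  sides <- sideMmToPx(scalesMm, image@pixelSizeMm)
  bigSpec <- patchSpec(sideMm = scalesMm[1],
                       pixelSizeMm = image@pixelSizeMm,
                       sidePx = max(sides),
                       minInsideFraction = patchSpecTemplate@minInsideFraction,
                       nPerClassTarget = patchSpecTemplate@nPerClassTarget,
                       densityPerMm2 = patchSpecTemplate@densityPerMm2,
                       seed = patchSpecTemplate@seed)
  big <- sampleTestingPatches(image, mask, bigSpec)
  centers <- cbind(patchInfo(big)$centerRow, patchInfo(big)$centerCol)
  perScale <- vector("list", length(scalesMm))
  for (k in seq_along(scalesMm)) {
    spk <- patchSpec(sideMm = scalesMm[k], pixelSizeMm = image@pixelSizeMm,
                     sidePx = sides[k],
                     minInsideFraction = patchSpecTemplate@minInsideFraction,
                     seed = patchSpecTemplate@seed)
    patches <- sampleTestingPatches(image, mask, spk, centers = centers)
    tab <- buildFeatureTable(patches, config)
    perScale[[k]] <- patchProbabilities(models[[k]], tab)
  }
  avg <- multiscaleAverage(perScale)
  map <- biharmonicInterpolate(avg, mask)
  list(map = map, centers = avg)
}
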