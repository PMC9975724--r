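# Synthetic bread-loaf specimen generator.
#
# The forward model reproduces the qualitative contrast regime of
# EGFR-targeted fluorescence in head-and-neck specimens: normal tissue is
# homogeneous in intensity and spatially ordered (a smooth correlated random
# field), tumor is brighter on average but heterogeneous and spatially
# disordered (random elliptical blobs plus unsmoothed noise), a bright
# low-variance "mucosa" band runs along the specimen edge (false-positive
# trap for intensity thresholding) and a dark "necrotic" core sits inside the
# tumor (false-negative trap). Intensity histograms of the two tissue classes
# overlap by construction.

#' Construct a SceneSpec with study-condition defaults
#'
#' Defaults encode the designed regime: normal mean 0.35 / sd 0.12 with a
#' 12-px correlation length; tumor mean 0.55 / sd 0.15 built from ~6-px blobs
#' plus white disorder noise (sd 0.10); mucosa mean 0.65 / sd 0.05; necrotic
#' core mean 0.20; dose scales 0.5 / 1.0 / 1.6 for groups 1/2/3. The tumor
#' ellipse (~30 mm^2) and tissue ellipse (~160 mm^2) give ROI areas on the
#' scale reported for real bread-loafed slices.
#'
#' @param imageHeightPx,imageWidthPx image size in pixels (default 480).
#' @param pixelSizeMm pixel size in mm (default 0.042).
#' @param doseGroup dose group 1..3.
#' @param doseScale brightness multiplier; default chosen by `doseGroup`
#'   from `c(0.5, 1, 1.6)`.
#' @param tissueGeometry,tumorGeometry lists with elements `centerFrac` (or
#'   `centerOffsetFrac` for the tumor), `radiiPx`, `roughness`, `nHarmonics`.
#' @param mucosaBandWidthPx width of the bright edge band in px (default 8).
#' @param necrosisFraction area fraction of tumor occupied by the dark core.
#' @param normalTexture list(mean, sd, correlationLengthPx).
#' @param tumorTexture list(mean, sd, blobScalePx, disorderSd).
#' @param mucosaTexture list(mean, sd).
#' @param necrosisMean mean intensity of the necrotic core.
#' @param backgroundLevel constant background intensity.
#' @param calibrationTargetValue calibration patch intensity (pre-dose).
#' @param seed integer RNG seed.
#' @return A [SceneSpec-class] object.
#' @export
sceneSpec <- function(imageHeightPx = 480L, imageWidthPx = 480L,
                      pixelSizeMm = 0.042, doseGroup = 2L,
                      doseScale = c(0.5, 1, 1.6)[doseGroup],
                      tissueGeometry = list(centerFrac = c(0.5, 0.5),
                                            radiiPx = c(190, 155),
                                            roughness = 0.08, nHarmonics = 5L),
                      tumorGeometry = list(centerOffsetFrac = c(0.1, -0.08),
                                           radiiPx = c(85, 68),
                                           roughness = 0.15, nHarmonics = 5L),
                      mucosaBandWidthPx = 8L, necrosisFraction = 0.12,
                      normalTexture = list(mean = 0.35, sd = 0.12,
                                           correlationLengthPx = 12),
                      tumorTexture = list(mean = 0.55, sd = 0.15,
                                          blobScalePx = 6, disorderSd = 0.10),
                      mucosaTexture = list(mean = 0.65, sd = 0.05),
                      necrosisMean = 0.20, backgroundLevel = 0.05,
                      calibrationTargetValue = 1, seed = 1L) {
  new("SceneSpec",
      imageHeightPx = as.integer(imageHeightPx),
      imageWidthPx = as.integer(imageWidthPx),
      pixelSizeMm = pixelSizeMm, doseGroup = as.integer(doseGroup),
      doseScale = doseScale, tissueGeometry = tissueGeometry,
      tumorGeometry = tumorGeometry,
      mucosaBandWidthPx = as.integer(mucosaBandWidthPx),
      necrosisFraction = necrosisFraction, normalTexture = normalTexture,
      tumorTexture = tumorTexture, mucosaTexture = mucosaTexture,
      necrosisMean = necrosisMean, backgroundLevel = backgroundLevel,
      calibrationTargetValue = calibrationTargetValue,
      seed = as.integer(seed))
}

# Separable Gaussian smoothing with truncated-kernel renormalisation at the
# borders (equivalent to replicate-free normalised convolution).
smoothGaussian <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  bandMat <- function(n) {
    m <- matrix(0, n, n)
    for (d in (-min(r, n - 1L)):min(r, n - 1L)) {
      idx <- seq_len(n - abs(d))
      if (d >= 0) m[cbind(idx, idx + d)] <- k[d + r + 1]
      else m[cbind(idx - d, idx)] <- k[d + r + 1]
    }
    m / rowSums(m)
  }
  Kr <- bandMat(nrow(x))
  Kc <- bandMat(ncol(x))
  Kr %*% x %*% t(Kc)
}

# Unit-variance smooth Gaussian random field on an nr x nc grid.
gaussianRandomField <- function(nr, nc, correlationLengthPx) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  z <- smoothGaussian(z, correlationLengthPx / 2)
  (z - mean(z)) / stats::sd(as.vector(z))
}

# Random low-order harmonic boundary perturbation; returns a function of the
# polar angle, bounded to +/- 0.3.
randomBoundary <- function(roughness, nHarmonics) {
  if (roughness <= 0 || nHarmonics < 1L) return(function(theta) 0 * theta)
  a <- rnorm(nHarmonics)
  b <- rnorm(nHarmonics)
  function(theta) {
    out <- 0
    for (kk in seq_len(nHarmonics))
      out <- out + a[kk] * cos(kk * theta) + b[kk] * sin(kk * theta)
    pmax(pmin(roughness * out / sqrt(nHarmonics), 0.3), -0.3)
  }
}

# Normalised elliptical radius and polar angle of every pixel w.r.t. a
# center (rows/cols are 1-based).
ellipseRho <- function(nr, nc, center, radii) {
  dr <- matrix(seq_len(nr) - center[1], nr, nc)
  dc <- matrix(seq_len(nc) - center[2], nr, nc, byrow = TRUE)
  list(rho = sqrt((dr / radii[1])^2 + (dc / radii[2])^2),
       theta = atan2(dc, dr))
}

# Sum of random anisotropic Gaussian blobs over a bounding box; the spatial
# disorder component of the tumor texture.
blobField <- function(nr, nc, regionMask, blobScalePx) {
  field <- matrix(0, nr, nc)
  area <- sum(regionMask)
  if (area == 0) return(field)
  nBlobs <- rpois(1, max(5, 1.5 * area / (pi * blobScalePx^2)))
  idx <- which(regionMask, arr.ind = TRUE)
  rlo <- min(idx[, 1]); rhi <- max(idx[, 1])
  clo <- min(idx[, 2]); chi <- max(idx[, 2])
  for (b in seq_len(nBlobs)) {
    cr <- runif(1, rlo, rhi); cc <- runif(1, clo, chi)
    sx <- blobScalePx * runif(1, 0.6, 1.6)
    sy <- blobScalePx * runif(1, 0.6, 1.6)
    th <- runif(1, 0, pi)
    amp <- rnorm(1)
    w <- ceiling(3 * max(sx, sy))
    rr <- max(1, floor(cr - w)):min(nr, ceiling(cr + w))
    cs <- max(1, floor(cc - w)):min(nc, ceiling(cc + w))
    dr <- matrix(rr - cr, length(rr), length(cs))
    dc <- matrix(cs - cc, length(rr), length(cs), byrow = TRUE)
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    field[rr, cs] <- field[rr, cs] + amp * exp(-(u^2 / (2 * sx^2) +
                                                 v^2 / (2 * sy^2)))
  }
  field
}

#' Generate one synthetic specimen (image + co-registered label mask)
#'
#' Renders the forward model described in [sceneSpec()]: an irregular tissue
#' ellipse filled with a smooth correlated normal field; a tumor sub-ellipse
#' filled with blob-plus-noise texture; an optional bright mucosa band along
#' the specimen edge (labeled normal) and a dark necrotic core inside the
#' tumor (labeled tumor); a constant-intensity calibration patch in the
#' background corner. All intensities are multiplied by the dose scale and
#' clipped at zero. Output is bit-reproducible for a given spec.
#'
#' @param spec a [SceneSpec-class].
#' @param specimenId identifier for the generated specimen.
#' @return A [SyntheticSpecimen-class].
#' @export
generateSpecimen <- function(spec, specimenId = sprintf("s%d", spec@seed)) {
  validObject(spec)
  set.seed(spec@seed)
  nr <- spec@imageHeightPx; nc <- spec@imageWidthPx
  tg <- spec@tissueGeometry; ug <- spec@tumorGeometry

  tissueCenter <- c(tg$centerFrac[1] * nr, tg$centerFrac[2] * nc)
  tb <- randomBoundary(tg$roughness, tg$nHarmonics)
  te <- ellipseRho(nr, nc, tissueCenter, tg$radiiPx)
  tissueBdry <- 1 + tb(te$theta)
  tissue <- te$rho <= tissueBdry
  rhoNorm <- te$rho / tissueBdry

  tumorCenter <- tissueCenter + ug$centerOffsetFrac * tg$radiiPx
  ub <- randomBoundary(ug$roughness, ug$nHarmonics)
  ue <- ellipseRho(nr, nc, tumorCenter, ug$radiiPx)
  tumorBdry <- 1 + ub(ue$theta)
  tumor <- ue$rho <= tumorBdry
  tumorRhoNorm <- ue$rho / tumorBdry

  if (!any(tumor)) stop("degenerate geometry: empty tumor region")
  if (!all(tissue[tumor])) stop("degenerate geometry: tumor not inside tissue")
  if (sum(tissue & !tumor) == 0)
    stop("degenerate geometry: empty normal region")

  bandFrac <- spec@mucosaBandWidthPx / mean(tg$radiiPx)
  mucosa <- tissue & !tumor & rhoNorm >= 1 - bandFrac
  if (any(mucosa & tumor)) stop("degenerate geometry: tumor reaches the edge")
  necrosis <- tumor & tumorRhoNorm <= sqrt(spec@necrosisFraction)

  img <- matrix(spec@backgroundLevel, nr, nc)

  nt <- spec@normalTexture
  normalField <- nt$mean + nt$sd *
    gaussianRandomField(nr, nc, nt$correlationLengthPx)
  normalPix <- tissue & !tumor & !mucosa
  img[normalPix] <- normalField[normalPix]

  if (any(mucosa)) {
    mt <- spec@mucosaTexture
    mucosaField <- mt$mean + mt$sd *
      gaussianRandomField(nr, nc, nt$correlationLengthPx)
    img[mucosa] <- mucosaField[mucosa]
  }

  tt <- spec@tumorTexture
  blobs <- blobField(nr, nc, tumor, tt$blobScalePx)
  bsd <- stats::sd(blobs[tumor])
  targetSd <- sqrt(max(tt$sd^2 - tt$disorderSd^2, 1e-4))
  if (is.finite(bsd) && bsd > 0)
    blobs <- (blobs - mean(blobs[tumor])) / bsd * targetSd
  tumorField <- tt$mean + blobs +
    matrix(rnorm(nr * nc, 0, tt$disorderSd), nr, nc)
  img[tumor] <- tumorField[tumor]

  if (any(necrosis)) {
    necField <- spec@necrosisMean + 0.03 *
      gaussianRandomField(nr, nc, nt$correlationLengthPx / 2)
    img[necrosis] <- necField[necrosis]
  }

  # constant calibration patch in the background near the top-left corner
  calSide <- 12L
  calRows <- 8L + seq_len(calSide); calCols <- 8L + seq_len(calSide)
  if (any(tissue[calRows, calCols]))
    stop("degenerate geometry: tissue overlaps the calibration patch")
  img[calRows, calCols] <- spec@calibrationTargetValue

  img <- pmax(img * spec@doseScale, 0)

  labels <- matrix(0L, nr, nc)
  labels[tissue] <- 1L
  labels[tumor] <- 2L

  image <- SpecimenImage(img, pixelSizeMm = spec@pixelSizeMm,
                         specimenId = specimenId,
                         doseGroup = spec@doseGroup,
                         calibrationValue = spec@calibrationTargetValue *
                           spec@doseScale)
  new("SyntheticSpecimen", image = image, mask = LabelMask(labels),
      spec = spec)
}

#' Generate a cohort of synthetic specimens across the three dose groups
#'
#' Produces `3 * nPerGroup` specimens; each dose group's brightness is scaled
#' by its entry of `doseScales`, and each specimen receives independently
#' jittered geometry. A single cohort seed drives per-specimen derived seeds
#' (`seed + index` for the texture stream, a disjoint offset for the geometry
#' jitter), so the cohort is reproducible and its members independent.
#'
#' @param nPerGroup specimens per dose group (default 8, i.e. 24 total).
#' @param baseSpec template [SceneSpec-class]; per-specimen specs are derived
#'   from it.
#' @param seed cohort-level integer seed.
#' @param doseScales numeric length-3 brightness multipliers per dose group.
#' @return list of [SyntheticSpecimen-class], group-major order.
#' @export
generateCohort <- function(nPerGroup = 8L, baseSpec = sceneSpec(),
                           seed = 1L, doseScales = c(0.5, 1, 1.6)) {
  stopifnot(nPerGroup >= 1L, length(doseScales) == 3L)
  out <- vector("list", 3L * nPerGroup)
  idx <- 0L
  for (g in 1:3) {
    for (i in seq_len(nPerGroup)) {
      idx <- idx + 1L
      set.seed((seed + 1000000L + idx) %% .Machine$integer.max)
      spec <- baseSpec
      spec@doseGroup <- g
      spec@doseScale <- doseScales[g]
      spec@seed <- as.integer((seed + idx) %% .Machine$integer.max)
      tg <- spec@tissueGeometry
      ug <- spec@tumorGeometry
      tg$radiiPx <- tg$radiiPx * runif(2, 0.88, 1.12)
      ug$radiiPx <- ug$radiiPx * runif(2, 0.85, 1.1)
      ug$centerOffsetFrac <- runif(2, -0.15, 0.15)
      spec@tissueGeometry <- tg
      spec@tumorGeometry <- ug
      spec@necrosisFraction <- spec@necrosisFraction * runif(1, 0.7, 1.3)
      out[[idx]] <- generateSpecimen(
        spec, specimenId = sprintf("g%d_s%02d", g, idx))
    }
  }
  out
}
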