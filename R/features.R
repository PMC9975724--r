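# Optomic feature extraction: 92 base features per patch (18 first-order +
# 23 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM), repeated on each member
# of the filter bank, giving 92 * (1 + 15) = 1,472 features with the default
# bank. Texture matrices are built by compiled kernels (src/textures.cpp);
# all formulas follow the IBSI reference nomenclature with explicit
# degenerate-case conventions so every output is finite.

plog2p <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

# Offsets for the four 2-D angles 0, 45, 90, 135 degrees.
angleOffsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

#' Discretize a patch into fixed-count gray levels
#'
#' Fixed bin count over the patch's own min-max range; half-open bins with
#' the last bin closed. A constant patch maps to a single level (Ng = 1).
#'
#' @param x numeric patch matrix.
#' @param nBins number of gray levels (default 32).
#' @return list(levels = integer matrix in 1..ng, ng, binEdges).
#' @export
discretizePatch <- function(x, nBins = 32L) {
  stopifnot(nBins >= 2L)
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    lev <- matrix(1L, nrow(x), ncol(x))
    return(list(levels = lev, ng = 1L, binEdges = c(lo, hi)))
  }
  lev <- pmin(floor((x - lo) / (hi - lo) * nBins) + 1L, nBins)
  storage.mode(lev) <- "integer"
  list(levels = lev, ng = max(lev), binEdges = seq(lo, hi,
                                                   length.out = nBins + 1L))
}

#' First-order intensity features (18)
#'
#' Distribution statistics of the raw patch intensities; entropy and
#' uniformity are computed on the discretized histogram. Conventions:
#' 0 log 0 = 0; skewness and kurtosis of a constant patch are 0; variance is
#' the population variance.
#'
#' @param x numeric patch matrix.
#' @param disc output of [discretizePatch()] for `x`.
#' @param pixelSizeMm pixel size, used for the total-energy pixel area.
#' @return named numeric vector of length 18.
#' @export
firstOrderFeatures <- function(x, disc = discretizePatch(x),
                               pixelSizeMm = 0.042) {
  v <- as.vector(x)
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  hist <- tabulate(as.vector(disc$levels), disc$ng)
  p <- hist / n
  q <- quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  mid <- v[v >= q[1] & v <= q[5]]
  c(Energy = sum(v^2),
    TotalEnergy = pixelSizeMm^2 * sum(v^2),
    Entropy = -sum(plog2p(p)),
    Minimum = min(v),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(v),
    Mean = m,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - m)),
    RobustMeanAbsoluteDeviation =
      if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((v - m)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

# Cache of the level-index grids reused by every GLCM evaluation at a given
# number of gray levels.
.glcmGrids <- new.env(parent = emptyenv())

glcmGrid <- function(ng) {
  key <- as.character(ng)
  g <- .glcmGrids[[key]]
  if (is.null(g)) {
    i <- seq_len(ng)
    iMat <- matrix(i, ng, ng)
    jMat <- t(iMat)
    dMat <- iMat - jMat
    g <- list(iMat = iMat, jMat = jMat, dMat = dMat, absD = abs(dMat),
              d2 = dMat^2, sMat = iMat + jMat,
              absDvec = as.vector(abs(dMat)), sVec = as.vector(iMat + jMat),
              prodIJ = iMat * jMat, offDiag = dMat != 0)
    .glcmGrids[[key]] <- g
  }
  g
}

glcmFeaturesOneAngle <- function(counts, ng) {
  tot <- sum(counts)
  p <- counts / tot
  i <- seq_len(ng)
  px <- rowSums(p)
  ux <- sum(i * px)
  varx <- sum((i - ux)^2 * px)
  gr <- glcmGrid(ng)
  iMat <- gr$iMat
  jMat <- gr$jMat
  dMat <- gr$dMat
  sMat <- gr$sMat
  # difference and sum distributions (rowsum groups are sorted ascending)
  pd <- as.vector(rowsum(as.vector(p), gr$absDvec))
  ps <- as.vector(rowsum(as.vector(p), gr$sVec))
  kd <- 0:(ng - 1L)
  ks <- 2:(2 * ng)
  da <- sum(kd * pd)
  autoc <- sum(gr$prodIJ * p)
  jointEntropy <- -sum(plog2p(p))
  hx <- -sum(plog2p(px))
  lpx <- ifelse(px > 0, log2(px), 0)
  hxy1 <- -sum(p * (matrix(lpx, ng, ng) + matrix(lpx, ng, ng, byrow = TRUE)))
  pxpy <- outer(px, px)
  hxy2 <- -sum(plog2p(pxpy))
  imc1 <- if (hx > 0) (jointEntropy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - jointEntropy)), 0))
  mcc <- {
    keep <- px > 0
    if (sum(keep) < 2L) 1 else {
      # Q = Dr^-1 (P Dc^-1 P^T) has the eigenvalues of the symmetric
      # Dr^-1/2 (P Dc^-1 P^T) Dr^-1/2; the MCC is sqrt of the second largest.
      Pk <- p[keep, keep, drop = FALSE]
      pk <- px[keep]
      M <- tcrossprod(Pk %*% (diag(1 / pk, length(pk))), Pk)
      S <- M / sqrt(outer(pk, pk))
      ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
      sqrt(pmax(ev[2], 0))
    }
  }
  sCen <- sMat - 2 * ux
  sCen2 <- sCen * sCen
  c(Autocorrelation = autoc,
    ClusterProminence = sum(sCen2 * sCen2 * p),
    ClusterShade = sum(sCen2 * sCen * p),
    ClusterTendency = sum(sCen2 * p),
    Contrast = sum(gr$d2 * p),
    Correlation = if (varx > 0) (autoc - ux^2) / varx else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(plog2p(pd)),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = sum(p / (1 + gr$absD)),
    Idm = sum(p / (1 + gr$d2)),
    Idmn = sum(p / (1 + gr$d2 / ng^2)),
    Idn = sum(p / (1 + gr$absD / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (ng > 1) sum(p[gr$offDiag] / gr$d2[gr$offDiag])
                      else 0,
    JointAverage = ux,
    JointEnergy = sum(p^2),
    JointEntropy = jointEntropy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumEntropy = -sum(plog2p(ps)),
    SumSquares = varx)
}

#' Gray-level co-occurrence features (23), angle-averaged
#'
#' Symmetric normalized GLCM at distance `distance` for the four 2-D angles;
#' features computed per angle and then averaged. Constant-patch
#' conventions: contrast 0, correlation 1, joint entropy 0, MCC 1.
#'
#' @param disc output of [discretizePatch()].
#' @param distance offset distance in pixels (default 1).
#' @return named numeric vector of length 23.
#' @export
glcmFeatures <- function(disc, distance = 1L) {
  per <- lapply(angleOffsets, function(o) {
    counts <- glcm_counts(disc$levels, disc$ng, o[1] * distance,
                          o[2] * distance)
    glcmFeaturesOneAngle(counts, disc$ng)
  })
  rowMeans(do.call(cbind, per))
}

.rlmGrids <- new.env(parent = emptyenv())

rlmGrid <- function(ng, L) {
  key <- paste0(ng, "x", L)
  g <- .rlmGrids[[key]]
  if (is.null(g)) {
    iMat <- matrix(seq_len(ng), ng, L)
    lMat <- matrix(seq_len(L), ng, L, byrow = TRUE)
    g <- list(iMat = iMat, lMat = lMat, i2 = iMat^2, l2 = lMat^2)
    .rlmGrids[[key]] <- g
  }
  g
}

rlmFeaturesOneAngle <- function(P, ng, np) {
  nr <- sum(P)
  p <- P / nr
  gr <- rlmGrid(ng, ncol(P))
  iMat <- gr$iMat
  lMat <- gr$lMat
  mu_i <- sum(p * iMat)
  mu_l <- sum(p * lMat)
  rs <- rowSums(P)
  cs <- colSums(P)
  c(ShortRunEmphasis = sum(P / gr$l2) / nr,
    LongRunEmphasis = sum(P * gr$l2) / nr,
    GrayLevelNonUniformity = sum(rs^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rs^2) / nr^2,
    RunLengthNonUniformity = sum(cs^2) / nr,
    RunLengthNonUniformityNormalized = sum(cs^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum(p * (iMat - mu_i)^2),
    RunVariance = sum(p * (lMat - mu_l)^2),
    RunEntropy = -sum(plog2p(p)),
    LowGrayLevelRunEmphasis = sum(P / gr$i2) / nr,
    HighGrayLevelRunEmphasis = sum(P * gr$i2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (gr$i2 * gr$l2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * gr$i2 / gr$l2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * gr$l2 / gr$i2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * gr$i2 * gr$l2) / nr)
}

#' Gray-level run-length features (16), angle-averaged over 4 directions
#'
#' @param disc output of [discretizePatch()].
#' @return named numeric vector of length 16.
#' @export
glrlmFeatures <- function(disc) {
  np <- length(disc$levels)
  per <- lapply(angleOffsets, function(o) {
    P <- glrlm_counts(disc$levels, disc$ng, o[1], o[2])
    rlmFeaturesOneAngle(P, disc$ng, np)
  })
  rowMeans(do.call(cbind, per))
}

#' Gray-level size-zone features (16)
#'
#' Zones are 8-connected constant-level regions.
#'
#' @param disc output of [discretizePatch()].
#' @return named numeric vector of length 16.
#' @export
glszmFeatures <- function(disc) {
  zones <- glszm_zones(disc$levels)
  np <- length(disc$levels)
  nz <- nrow(zones)
  i <- zones[, 1]
  s <- zones[, 2]
  # zone-count weights per (level, size) cell are implicit: iterate zones
  mu_i <- mean(i)
  mu_s <- mean(s)
  p <- rep(1 / nz, nz)
  # cell counts over (level, size) for zone entropy and non-uniformities
  maxS <- max(s)
  cellP <- tabulate((i - 1L) * maxS + s, disc$ng * maxS)
  cellP <- cellP[cellP > 0] / nz
  gln <- sum(tabulate(i, disc$ng)^2)
  szn <- sum(tabulate(s, maxS)^2)
  c(SmallAreaEmphasis = sum(1 / s^2) / nz,
    LargeAreaEmphasis = sum(s^2) / nz,
    GrayLevelNonUniformity = gln / nz,
    GrayLevelNonUniformityNormalized = gln / nz^2,
    SizeZoneNonUniformity = szn / nz,
    SizeZoneNonUniformityNormalized = szn / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    ZoneVariance = sum(p * (s - mu_s)^2),
    ZoneEntropy = -sum(plog2p(cellP)),
    LowGrayLevelZoneEmphasis = sum(1 / i^2) / nz,
    HighGrayLevelZoneEmphasis = sum(i^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(1 / (i^2 * s^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(i^2 / s^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(s^2 / i^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(i^2 * s^2) / nz)
}

#' Gray-level dependence features (14)
#'
#' Dependence of a pixel is 1 plus the number of its 8-neighbours whose
#' level difference is at most `alpha` (the center counts itself, keeping
#' all emphases finite).
#'
#' @param disc output of [discretizePatch()].
#' @param alpha dependence threshold on the level difference (default 0).
#' @return named numeric vector of length 14.
#' @export
gldmFeatures <- function(disc, alpha = 0L) {
  P <- gldm_counts(disc$levels, disc$ng, alpha)
  nz <- sum(P)
  p <- P / nz
  ng <- disc$ng
  i <- seq_len(ng)
  j <- 1:9
  iMat <- matrix(i, ng, 9)
  jMat <- matrix(j, ng, 9, byrow = TRUE)
  mu_i <- sum(p * iMat)
  mu_j <- sum(p * jMat)
  c(SmallDependenceEmphasis = sum(P / jMat^2) / nz,
    LargeDependenceEmphasis = sum(P * jMat^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    GrayLevelVariance = sum(p * (iMat - mu_i)^2),
    DependenceVariance = sum(p * (jMat - mu_j)^2),
    DependenceEntropy = -sum(plog2p(p)),
    LowGrayLevelEmphasis = sum(P / iMat^2) / nz,
    HighGrayLevelEmphasis = sum(P * iMat^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (iMat^2 * jMat^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * iMat^2 / jMat^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * jMat^2 / iMat^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * iMat^2 * jMat^2) / nz)
}

#' Neighborhood gray-tone difference features (5)
#'
#' Chebyshev-radius-1 neighbourhood. Degenerate conventions: coarseness of a
#' constant patch is capped at 1e6; contrast, busyness and strength are 0
#' when undefined.
#'
#' @param disc output of [discretizePatch()].
#' @return named numeric vector of length 5.
#' @export
ngtdmFeatures <- function(disc) {
  st <- ngtdm_stats(disc$levels, disc$ng)
  nvox <- sum(st[, 1])
  p <- st[, 1] / nvox
  s <- st[, 2]
  i <- seq_len(disc$ng)
  present <- p > 0
  ngp <- sum(present)
  ip <- i[present]; pp <- p[present]; sp <- s[present]
  psSum <- sum(pp * sp)
  coarseness <- if (psSum > 0) min(1 / psSum, 1e6) else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(pp, pp) * outer(ip, ip, "-")^2) / (ngp * (ngp - 1)) *
      sum(sp) / nvox
  } else 0
  busyDenom <- sum(abs(outer(ip * pp, ip * pp, "-")))
  busyness <- if (busyDenom > 0) psSum / busyDenom else 0
  complexity <- if (ngp > 1) {
    num <- outer(pp * sp, pp * sp, "+")
    den <- outer(pp, pp, "+")
    sum(abs(outer(ip, ip, "-")) * num / den) / nvox
  } else 0
  strength <- if (sum(sp) > 0) {
    sum(outer(pp, pp, "+") * outer(ip, ip, "-")^2) / sum(sp)
  } else 0
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

#' Default feature-extraction configuration
#'
#' @param nBins gray levels for discretization (default 32).
#' @param filters character vector of filter names ([defaultFilterBank()] by
#'   default; `character(0)` gives the raw-only 92-feature vector).
#' @param pixelSizeMm pixel size in mm.
#' @param glcmDistance co-occurrence offset distance in pixels.
#' @return list configuration consumed by [extractFeatures()].
#' @export
featureConfig <- function(nBins = 32L, filters = defaultFilterBank(),
                          pixelSizeMm = 0.042, glcmDistance = 1L) {
  list(nBins = as.integer(nBins), filters = filters,
       pixelSizeMm = pixelSizeMm, glcmDistance = as.integer(glcmDistance))
}

# Compute all 92 base features for one image matrix.
baseFeatureVector <- function(x, config) {
  disc <- discretizePatch(x, config$nBins)
  fo <- firstOrderFeatures(x, disc, config$pixelSizeMm)
  gl <- glcmFeatures(disc, config$glcmDistance)
  rl <- glrlmFeatures(disc)
  sz <- glszmFeatures(disc)
  dm <- gldmFeatures(disc)
  nt <- ngtdmFeatures(disc)
  c(setNames(fo, paste0("firstorder_", names(fo))),
    setNames(gl, paste0("glcm_", names(gl))),
    setNames(rl, paste0("glrlm_", names(rl))),
    setNames(sz, paste0("glszm_", names(sz))),
    setNames(dm, paste0("gldm_", names(dm))),
    setNames(nt, paste0("ngtdm_", names(nt))))
}

#' Extract the full optomic feature vector of one patch
#'
#' Computes the 92 base features on the raw patch and on each filter-bank
#' output; names follow `<filter>_<family>_<feature>` with filter
#' `original` for the raw patch. With the default 15-filter bank the vector
#' has length 1,472.
#'
#' @param x numeric patch matrix (standardized intensities).
#' @param config a [featureConfig()] list.
#' @return named numeric vector of length `92 * (1 + length(filters))`.
#' @export
extractFeatures <- function(x, config = featureConfig()) {
  base <- baseFeatureVector(x, config)
  out <- setNames(base, paste0("original_", names(base)))
  for (f in config$filters) {
    fx <- applyFilter(x, f, config$pixelSizeMm)
    fv <- baseFeatureVector(fx, config)
    out <- c(out, setNames(fv, paste0(gsub("[-.]", "", f), "_", names(fv))))
  }
  out
}

#' Build a feature table (SummarizedExperiment) from a PatchSet
#'
#' Rows are features, columns are patches; `colData` carries the patch
#' provenance (specimen, center, scale, label).
#'
#' @param patches a [PatchSet-class].
#' @param config a [featureConfig()] list; its `pixelSizeMm` defaults to the
#'   PatchSet's.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"optomics"`; `metadata(x)$standardized` is FALSE.
#' @export
buildFeatureTable <- function(patches, config = featureConfig(
                                pixelSizeMm = patches@pixelSizeMm)) {
  n <- length(patches)
  if (n == 0) stop("empty PatchSet")
  first <- extractFeatures(patches[[1]], config)
  mat <- matrix(0, length(first), n,
                dimnames = list(names(first), NULL))
  mat[, 1] <- first
  if (n > 1) {
    for (k in 2:n) mat[, k] <- extractFeatures(patches[[k]], config)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(optomics = mat),
    colData = S4Vectors::DataFrame(patchInfo(patches)),
    metadata = list(standardized = FALSE, config = config))
}

#' Z-score standardize a feature table
#'
#' Per-feature `(x - mu) / sd`. When `stats` is omitted the statistics are
#' computed from the table itself (training use); a test table must supply
#' the training statistics. Zero-variance features are set to 0 and flagged
#' in `metadata(x)$zeroVariance`.
#'
#' @param table a feature SummarizedExperiment from [buildFeatureTable()].
#' @param stats optional data.frame(feature, mu, sd) from a training table
#'   (stored in `metadata(x)$stats` after standardization).
#' @return the standardized SummarizedExperiment.
#' @export
zscoreStandardize <- function(table, stats = NULL) {
  mat <- SummarizedExperiment::assay(table, "optomics")
  if (is.null(stats)) {
    mu <- rowMeans(mat)
    sdv <- apply(mat, 1, stats::sd)
    stats <- data.frame(feature = rownames(mat), mu = mu, sd = sdv,
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(all(rownames(mat) %in% stats$feature))
    stats <- stats[match(rownames(mat), stats$feature), ]
    mu <- stats$mu
    sdv <- stats$sd
  }
  zero <- !is.finite(sdv) | sdv == 0
  z <- (mat - mu) / ifelse(zero, 1, sdv)
  z[zero, ] <- 0
  SummarizedExperiment::assay(table, "optomics") <- z
  md <- S4Vectors::metadata(table)
  md$standardized <- TRUE
  md$stats <- stats
  md$zeroVariance <- rownames(mat)[zero]
  S4Vectors::metadata(table) <- md
  table
}
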