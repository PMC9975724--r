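# Feature extraction: discretization, first-order statistics, texture
# families against brute-force enumeration, filters, vector contract and
# Z-score standardization.

test_that("discretization uses half-open fixed-count bins", {
  d <- discretizePatch(matrix(c(0, 0.5, 1), 1, 3), 2L)
  expect_identical(as.vector(d$levels), c(1L, 2L, 2L))
  dc <- discretizePatch(matrix(0.3, 3, 3))
  expect_identical(dc$ng, 1L)
  set.seed(1)
  d32 <- discretizePatch(matrix(runif(100), 10, 10), 32L)
  expect_lte(max(d32$levels), 32L)
  expect_gte(min(d32$levels), 1L)
})

test_that("first-order features match hand computation", {
  x <- matrix(c(1, 2, 3, 4), 2, 2)
  f <- firstOrderFeatures(x, discretizePatch(x, 4L))
  expect_equal(f[["Mean"]], 2.5)
  expect_equal(f[["Variance"]], 1.25)  # population variance
  expect_equal(f[["Range"]], 3)
  expect_equal(f[["Energy"]], 1 + 4 + 9 + 16)
  expect_equal(f[["RootMeanSquared"]], sqrt(30 / 4))

  xc <- matrix(0.4, 3, 3)
  fc <- firstOrderFeatures(xc, discretizePatch(xc))
  expect_equal(fc[["Mean"]], 0.4)
  expect_equal(fc[["Variance"]], 0)
  expect_equal(fc[["Entropy"]], 0)
  expect_equal(fc[["Energy"]], 9 * 0.16)
  expect_equal(fc[["Range"]], 0)
  expect_equal(fc[["Skewness"]], 0)
  expect_equal(fc[["Kurtosis"]], 0)

  # two values, equal counts, 2 bins: uniform histogram
  x2 <- matrix(rep(c(0.2, 0.8), 8), 4, 4)
  f2 <- firstOrderFeatures(x2, discretizePatch(x2, 2L))
  expect_equal(f2[["Uniformity"]], 0.5)
  expect_equal(f2[["Entropy"]], 1)
})

test_that("GLCM behaves on alternating and constant patterns", {
  # 1-D alternating strip at distance 1, angle 0: all pairs differ by 1
  lev <- matrix(c(1L, 2L, 1L, 2L), 1, 4)
  counts <- optomics:::glcm_counts(lev, 2L, 0L, 1L)
  expect_equal(sum(counts), 6)  # 3 offset pairs, symmetrized
  f <- optomics:::glcmFeaturesOneAngle(counts, 2L)
  expect_equal(f[["Contrast"]], 1)
  # normalization: probabilities sum to 1
  expect_equal(sum(counts / sum(counts)), 1)
  # constant patch conventions
  dc <- discretizePatch(matrix(0.7, 4, 4))
  fc <- glcmFeatures(dc)
  expect_equal(fc[["Contrast"]], 0)
  expect_equal(fc[["Correlation"]], 1)
  expect_equal(fc[["JointEntropy"]], 0)
  expect_equal(fc[["Idm"]], 1)
  expect_equal(fc[["MCC"]], 1)
})

test_that("GLRLM and GLSZM behave on constant and striped patterns", {
  # constant 4x4: one zone of size 16
  dc <- discretizePatch(matrix(0.7, 4, 4))
  z <- glszmFeatures(dc)
  expect_equal(z[["ZonePercentage"]], 1 / 16)
  expect_equal(z[["LargeAreaEmphasis"]], 256)
  # constant 4x4 at angle 0: 4 maximal runs of length 4
  P <- optomics:::glrlm_counts(dc$levels, 1L, 0L, 1L)
  expect_equal(sum(P), 4)
  expect_equal(optomics:::rlmFeaturesOneAngle(P, 1L, 16)[["LongRunEmphasis"]],
               16)
  # strictly increasing levels along each row: all runs have length 1
  lev <- matrix(rep(1:6, times = 6), 6, 6, byrow = TRUE)
  P1 <- optomics:::glrlm_counts(lev, 6L, 0L, 1L)
  f1 <- optomics:::rlmFeaturesOneAngle(P1, 6L, 36)
  expect_equal(f1[["RunPercentage"]], 1)
})

test_that("all texture families match brute-force enumeration", {
  for (p in oraclePatches()) {
    disc <- list(levels = p$lev, ng = p$ng)
    expect_equal(glcmFeatures(disc), oracleGlcmFeatures(p$lev, p$ng),
                 tolerance = 1e-10)
    expect_equal(glrlmFeatures(disc), oracleGlrlmFeatures(p$lev, p$ng),
                 tolerance = 1e-10)
    expect_equal(glszmFeatures(disc), oracleGlszmFeatures(p$lev, p$ng),
                 tolerance = 1e-10)
    expect_equal(gldmFeatures(disc), oracleGldmFeatures(p$lev, p$ng),
                 tolerance = 1e-10)
    expect_equal(ngtdmFeatures(disc), oracleNgtdmFeatures(p$lev, p$ng),
                 tolerance = 1e-10)
  }
})

test_that("angle-averaged GLCM/GLRLM features are 90-degree rotation
           invariant", {
  set.seed(8)
  for (rep in 1:3) {
    x <- matrix(runif(49), 7, 7)
    d1 <- discretizePatch(x)
    rot <- t(x)[, nrow(x):1]  # 90-degree rotation
    d2 <- discretizePatch(rot)
    expect_equal(glcmFeatures(d1), glcmFeatures(d2), tolerance = 1e-12)
    expect_equal(glrlmFeatures(d1), glrlmFeatures(d2), tolerance = 1e-12)
  }
})

test_that("filters behave on constant and monotone inputs", {
  xc <- matrix(0.6, 9, 9)
  expect_true(all(optomics:::haarHi(xc, 1L) == 0))
  expect_true(all(applyFilter(xc, "wavelet-HH") == 0))
  expect_true(all(applyFilter(xc, "gradient") == 0))
  set.seed(2)
  x <- matrix(runif(81), 9, 9)
  sq <- applyFilter(x, "square")
  expect_true(all(sq >= 0 & sq <= 1))
  expect_identical(order(as.vector(sq)), order(as.vector(x)))
  # LoG response shrinks with smoothing scale
  big <- optomics:::logFilter(x, 8)
  small <- optomics:::logFilter(x, 0.8)
  expect_lt(sqrt(mean(big^2)), sqrt(mean(small^2)))
})

test_that("the feature vector has the stated length, names and finiteness", {
  set.seed(4)
  x <- matrix(runif(21 * 21), 21, 21)
  full <- extractFeatures(x)
  expect_length(full, 1472L)
  raw <- extractFeatures(x, featureConfig(filters = character(0)))
  expect_length(raw, 92L)
  expect_identical(full, extractFeatures(x))  # determinism
  cases <- list(constant = matrix(0.3, 21, 21),
                binary = matrix(rep_len(c(0, 1), 441), 21, 21),
                random = x)
  for (cs in cases) {
    v <- extractFeatures(cs)
    expect_true(all(is.finite(v)))
    expect_length(v, 1472L)
  }
})

test_that("Z-score standardization centers training tables and flags
           degenerate features", {
  tab <- makeFakeTable(nSpec = 2L, nPerSpec = 20L, nFeat = 5L)
  mat <- SummarizedExperiment::assay(tab, "optomics")
  mat["feat05", ] <- 2.2  # constant column
  SummarizedExperiment::assay(tab, "optomics") <- mat
  z <- zscoreStandardize(tab)
  zm <- SummarizedExperiment::assay(z, "optomics")
  expect_equal(unname(rowMeans(zm)[1:4]), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(zm[1:4, ], 1, sd)), rep(1, 4),
               tolerance = 1e-12)
  expect_true(all(zm["feat05", ] == 0))
  expect_identical(S4Vectors::metadata(z)$zeroVariance, "feat05")
  # a shifted test table standardized with training stats is off-center
  tab2 <- makeFakeTable(nSpec = 2L, nPerSpec = 20L, nFeat = 5L, seed = 8L)
  m2 <- SummarizedExperiment::assay(tab2, "optomics") + 1
  SummarizedExperiment::assay(tab2, "optomics") <- m2
  z2 <- zscoreStandardize(tab2, stats = S4Vectors::metadata(z)$stats)
  expect_gt(max(abs(rowMeans(
    SummarizedExperiment::assay(z2, "optomics")[1:4, ]))), 0.2)
})
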