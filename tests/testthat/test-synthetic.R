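# Synthetic specimen generator: determinism, label structure, and the
# designed statistical regime (overlapping intensities, texture contrast,
# intensity-confounded thresholding).

test_that("generation is bit-identical under a fixed seed", {
  spec <- tinyScene(seed = 3L)
  a <- generateSpecimen(spec)
  b <- generateSpecimen(spec)
  expect_identical(pixels(a), pixels(b))
  expect_identical(maskLabels(a), maskLabels(b))
})

test_that("masks carry exactly the labels 0/1/2 and conserve pixel counts", {
  s <- tinySpecimen()
  lab <- maskLabels(s)
  expect_setequal(unique(as.vector(lab)), 0:2)
  tab <- tabulate(as.vector(lab) + 1L, 3L)
  expect_identical(sum(tab), length(lab))
  # tumor and normal regions sit inside the tissue support
  expect_true(all(lab[maskLabels(s) == 2L] != 0L))
})

test_that("without mucosa and necrosis, tumor is brighter on average", {
  spec <- tinyScene(seed = 5L)
  spec@necrosisFraction <- 0
  spec@mucosaBandWidthPx <- 0L
  s <- generateSpecimen(spec)
  lab <- maskLabels(s); px <- pixels(s)
  expect_setequal(unique(as.vector(lab)), 0:2)
  expect_gt(mean(px[lab == 2L]), mean(px[lab == 1L]))
})

test_that("tumor and normal intensity histograms overlap substantially", {
  s <- defaultStandardized()
  lab <- maskLabels(defaultSpecimen())
  set.seed(1)
  tum <- sample(s@pixels[lab == 2L], 10000)
  nor <- sample(s@pixels[lab == 1L], 10000)
  # histogram overlap coefficient by numerical integration over shared bins
  br <- seq(0, 1, length.out = 65)
  pT <- hist(tum, breaks = br, plot = FALSE)$counts / 10000
  pN <- hist(nor, breaks = br, plot = FALSE)$counts / 10000
  overlap <- sum(pmin(pT, pN))
  expect_gt(overlap, 0.2)
})

test_that("tumor patches show higher GLCM contrast than normal patches", {
  s <- defaultStandardized()
  mask <- LabelMask(maskLabels(defaultSpecimen()))
  spec <- patchSpec(nPerClassTarget = 50, seed = 2L)
  ps <- sampleTrainingPatches(s, mask, spec)
  info <- patchInfo(ps)
  contrast <- vapply(seq_len(length(ps)), function(i) {
    glcmFeatures(discretizePatch(ps[[i]]))[["Contrast"]]
  }, 0)
  expect_gte(sum(info$label == "malignant"), 50)
  expect_gte(sum(info$label == "non_malignant"), 50)
  expect_gt(mean(contrast[info$label == "malignant"]),
            mean(contrast[info$label == "non_malignant"]))
})

test_that("no global intensity threshold achieves perfect pixel accuracy", {
  s <- defaultStandardized()
  lab <- maskLabels(defaultSpecimen())
  roi <- lab >= 1L
  x <- s@pixels[roi]
  y <- lab[roi] == 2L
  # brute-force sweep over quantile candidates plus both extremes
  cand <- c(-Inf, quantile(x, seq(0, 1, 0.002), names = FALSE), Inf)
  accs <- vapply(cand, function(t)
    (sum(x >= t & y) + sum(x < t & !y)) / length(x), 0)
  expect_lt(max(accs), 1)
})

test_that("cohorts have 3 * nPerGroup specimens with per-group dose scaling", {
  co <- generateCohort(2L, tinyScene(), seed = 4L)
  expect_length(co, 6L)
  expect_identical(vapply(co, doseGroup, 0L), rep(1:3, each = 2L))
  expect_equal(vapply(co, function(s) s@spec@doseScale, 0),
               rep(c(0.5, 1, 1.6), each = 2L))
  one <- generateCohort(1L, tinyScene(), seed = 4L)
  expect_length(one, 3L)
  # repeatability
  co2 <- generateCohort(2L, tinyScene(), seed = 4L)
  expect_identical(lapply(co, pixels), lapply(co2, pixels))
})

test_that("degenerate geometry is rejected", {
  spec <- tinyScene(seed = 1L)
  spec@tumorGeometry$radiiPx <- c(90, 90)  # larger than the tissue
  expect_error(generateSpecimen(spec), "degenerate")
})
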