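# Patch sampling: containment rule, bounds safety, multi-scale geometry,
# and the testing-patch labeling rule.

test_that("a full-image ROI yields every in-bounds center", {
  mask <- LabelMask(matrix(1L, 100, 100))
  ctr <- validCenters(mask, 1L, patchSpec(sidePx = 43L))
  expect_equal(nrow(ctr), 58 * 58)
  expect_equal(range(ctr[, 1]), c(22, 79))
  expect_equal(range(ctr[, 2]), c(22, 79))
})

test_that("valid centers match brute-force window counting", {
  set.seed(21)
  for (rep in 1:3) {
    lab <- matrix(0L, 40, 40)
    # random blob-ish ROI
    ctr <- cbind(sample(10:30, 3), sample(10:30, 3))
    for (k in 1:3) {
      rr <- pmax(1, ctr[k, 1] - 8):pmin(40, ctr[k, 1] + 8)
      cc <- pmax(1, ctr[k, 2] - 6):pmin(40, ctr[k, 2] + 6)
      lab[rr, cc] <- 1L
    }
    spec <- patchSpec(sidePx = 9L, minInsideFraction = 0.9)
    got <- validCenters(LabelMask(lab), 1L, spec)
    want <- oracleValidCenters(lab, 1L, 9L, 0.9)
    expect_equal(unname(got), unname(want))
  }
})

test_that("too-small ROIs yield no centers; an exact square yields one", {
  lab <- matrix(0L, 60, 60)
  lab[20:29, 20:29] <- 1L  # area 100 < 0.9 * 43^2
  expect_equal(nrow(validCenters(LabelMask(lab), 1L,
                                 patchSpec(sidePx = 43L))), 0)
  lab2 <- matrix(0L, 60, 60)
  lab2[10:52, 10:52] <- 1L  # exactly 43 x 43
  ctr <- validCenters(LabelMask(lab2), 1L,
                      patchSpec(sidePx = 43L, minInsideFraction = 1))
  expect_equal(unname(ctr), matrix(c(31, 31), 1))
})

test_that("training patches satisfy containment and stay in bounds", {
  s <- tinyStandardized()
  mask <- LabelMask(maskLabels(tinySpecimen()))
  spec <- patchSpec(sideMm = 0.9, nPerClassTarget = 25, seed = 5L)
  ps <- sampleTrainingPatches(s, mask, spec)
  info <- patchInfo(ps)
  h <- (spec@sidePx - 1) %/% 2
  expect_true(all(info$centerRow > h & info$centerRow <= nrow(s@pixels) - h))
  expect_true(all(info$centerCol > h & info$centerCol <= ncol(s@pixels) - h))
  roiOf <- c(non_malignant = 1L, malignant = 2L)
  for (i in seq_len(length(ps))) {
    win <- maskLabels(tinySpecimen())[
      (info$centerRow[i] - h):(info$centerRow[i] + h),
      (info$centerCol[i] - h):(info$centerCol[i] + h)]
    expect_gte(mean(win == roiOf[[info$label[i]]]), 0.9 - 1e-12)
  }
  # determinism
  ps2 <- sampleTrainingPatches(s, mask, spec)
  expect_identical(patchInfo(ps), patchInfo(ps2))
  expect_identical(ps@pixels, ps2@pixels)
})

test_that("the three scales map to 43, 33 and 21 pixels at 42 um", {
  expect_identical(sideMmToPx(c(1.8, 1.4, 0.9), 0.042), c(43L, 33L, 21L))
})

test_that("testing patches are labeled by the single-ROI coverage rule", {
  lab <- matrix(0L, 60, 60)
  lab[6:55, 6:30] <- 1L
  lab[6:55, 31:55] <- 2L
  img <- SpecimenImage(matrix(0.5, 60, 60), isStandardized = TRUE,
                       specimenId = "t")
  spec <- patchSpec(sidePx = 9L, seed = 1L)
  deep <- sampleTestingPatches(img, LabelMask(lab), spec,
                               centers = rbind(c(20, 40), c(20, 15),
                                               c(20, 31)))
  expect_identical(patchInfo(deep)$label,
                   c("malignant", "non_malignant", "unlabeled"))
  # no tissue, no patches
  none <- sampleTestingPatches(img, LabelMask(matrix(0L, 60, 60)), spec)
  expect_length(none, 0)
})

test_that("area-proportional sampling gives patch counts on the reported
           scale", {
  co <- fixture("smallCohort18", {
    generateCohort(8L, sceneSpec(), seed = 31L)[1:18]
  })
  spec <- patchSpec(seed = 2L)  # default density, 1.8 mm patches
  counts <- vapply(co, function(s) {
    std <- preprocessSpecimen(s)
    ps <- sampleTrainingPatches(std, s@mask, spec)
    sum(patchInfo(ps)$label == "malignant")
  }, 0)
  # reported per-specimen malignant patch counts were 204 +/- 167; the
  # synthetic geometry differs, so require the same order of magnitude
  expect_gt(mean(counts), 20.4)
  expect_lt(mean(counts), 2040)
})
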