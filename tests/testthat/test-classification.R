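# Partitioning, OCP fitting, grid search (incl. the no-leakage property),
# evaluation metrics and the paired comparison.

test_that("per-dose-group 75/25 partitioning aggregates to 18 + 6", {
  co <- lapply(1:24, function(i) {
    img <- SpecimenImage(matrix(0.5, 4, 4), specimenId = sprintf("s%02d", i),
                         doseGroup = ((i - 1) %/% 8) + 1)
    img
  })
  part <- partitionCohort(co, 0.75, seed = 2L)
  expect_length(part$train, 18L)
  expect_length(part$test, 6L)
  groups <- function(ids) table(((as.integer(sub("s", "", ids)) - 1) %/% 8) + 1)
  expect_true(all(groups(part$train) == 6))
  expect_true(all(groups(part$test) == 2))
  expect_identical(partitionCohort(co, 0.75, seed = 2L), part)
  expect_error(partitionCohort(co, 1.0, seed = 1L), "empty")
  expect_error(partitionCohort(co[1:9], 0.75, seed = 1L),
               "fewer than 2")
})

test_that("the OCP example is reproduced with the lowest-tie rule", {
  x <- c(0.6, 0.7, 0.9, 0.1, 0.2, 0.8)
  y <- c(1, 1, 1, 0, 0, 0)
  m <- fitOcp(x, y)
  expect_equal(m@trainAccuracy, 5 / 6)
  expect_equal(m@ocp, 0.4)  # smallest candidate (midpoint) in (0.2, 0.6]
  # perfectly separated classes
  m2 <- fitOcp(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(m2@trainAccuracy, 1)
  expect_gt(m2@ocp, 0.2)
  expect_lte(m2@ocp, 0.8)
  # inverting labels cannot beat the optimum
  mInv <- fitOcp(x, 1 - y)
  expect_lte(mInv@trainAccuracy, m@trainAccuracy)
  expect_error(fitOcp(x, rep(1, 6)), "both classes")
})

test_that("fitOcp equals the exhaustive sweep on random instances", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(10:1000, 1)
    x <- round(runif(n), sample(1:3, 1))  # ties are common
    y <- runif(n) < plogis(6 * (x - 0.5))
    if (length(unique(y)) < 2) next
    m <- fitOcp(x, y)
    o <- oracleOcp(x, y)
    expect_equal(m@trainAccuracy, o$accuracy)
    expect_equal(m@ocp, o$ocp)
  }
})

test_that("evaluation metrics follow the confusion-matrix identities", {
  # build a specimen whose ROI confusion matrix is TP=39 FN=1 FP=7 TN=73
  px <- matrix(0, 12, 10)
  lab <- matrix(0L, 12, 10)
  vals <- c(rep(0.9, 39), rep(0.1, 1),   # tumor pixels
            rep(0.9, 7), rep(0.1, 73))   # normal pixels
  labs <- c(rep(2L, 40), rep(1L, 80))
  px[seq_len(120)] <- vals
  lab[seq_len(120)] <- labs
  img <- SpecimenImage(px, specimenId = "rep", isStandardized = TRUE)
  rep1 <- evaluateThresholding(new("ThresholdModel", ocp = 0.5,
                                   trainAccuracy = NA_real_),
                               list(img), list(LabelMask(lab)))
  row <- rep1@perSpecimen
  expect_equal(row$tp, 39); expect_equal(row$fn, 1)
  expect_equal(row$fp, 7); expect_equal(row$tn, 73)
  expect_equal(row$accuracy, (39 + 73) / 120)  # 93.3%
  expect_equal(row$fpr, 7 / 80)                # 8.75%
  expect_equal(row$fnr, 1 / 40)                # 2.5%
  expect_true(all(row[c("accuracy", "fpr", "fnr")] >= 0 &
                    row[c("accuracy", "fpr", "fnr")] <= 1))
})

fakeReport <- function(acc, fpr = acc * 0, fnr = acc * 0, method = "m") {
  n <- length(acc)
  new("EvalReport", method = method,
      perSpecimen = data.frame(specimenId = sprintf("s%d", seq_len(n)),
                               n = 10, tp = 1, fn = 1, fp = 1, tn = 1,
                               accuracy = acc, fpr = fpr, fnr = fnr),
      aggregate = c(accuracy = mean(acc), fpr = mean(fpr),
                    fnr = mean(fnr)))
}

test_that("paired comparison follows the t-test formula and conventions", {
  a <- fakeReport(c(0.9, 0.8, 0.85, 0.7, 0.95, 0.75))
  expect_equal(pairedCompare(a, a)$p, rep(1, 3))
  # differences {2,-1,3,0,1,1} (scaled down by 100 on the accuracy scale)
  d <- c(2, -1, 3, 0, 1, 1) / 100
  b <- fakeReport(a@perSpecimen$accuracy - d)
  cmp <- pairedCompare(a, b)
  tExpected <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(cmp$t[1], tExpected)
  expect_equal(cmp$p[1], 2 * pt(-abs(tExpected), df = 5))
  # zero variance, nonzero mean: p collapses to 0
  b2 <- fakeReport(a@perSpecimen$accuracy - 0.01)
  cmp2 <- pairedCompare(a, b2)
  expect_equal(cmp2$p[1], 0)
  expect_true(is.infinite(cmp2$t[1]))
  bad <- fakeReport(c(0.5, 0.5))
  expect_error(pairedCompare(a, bad), "different specimen sets")
})

test_that("the default grid enumerates 980 combinations", {
  g <- gridSpec()
  expect_equal(gridSize(g), 980L)
  expect_length(g$featureCounts, 20L)
  expect_identical(g$featureCounts, seq(5L, 100L, 5L))
})

test_that("a 1x1x1 grid returns its only combination and 1 fold per
           specimen", {
  tab <- makeFakeTable(nSpec = 4L, nPerSpec = 20L)
  g <- gridSpec(classifiers = "DT", selectors = "PRCC", featureCounts = 3L)
  res <- loocvGridSearch(tab, g, seed = 1L)
  expect_identical(res$best,
                   list(classifier = "DT", selector = "PRCC",
                        nFeatures = 3L))
  expect_identical(dim(res$foldAccuracy), c(4L, 1L, 1L, 1L))
})

test_that("corrupting the held-out specimen leaves in-fold artifacts
           unchanged", {
  tab <- makeFakeTable(nSpec = 4L, nPerSpec = 20L)
  g <- gridSpec(classifiers = "DT", selectors = c("PRCC", "MIM"),
                featureCounts = c(3L, 5L))
  res1 <- loocvGridSearch(tab, g, seed = 1L, returnArtifacts = TRUE)
  # corrupt one specimen's labels and features
  tab2 <- tab
  info <- SummarizedExperiment::colData(tab2)
  corrupt <- info$specimenId == "spec03"
  info$label[corrupt] <- "non_malignant"
  SummarizedExperiment::colData(tab2) <- info
  m <- SummarizedExperiment::assay(tab2, "optomics")
  m[, corrupt] <- m[, corrupt] + 100
  SummarizedExperiment::assay(tab2, "optomics") <- m
  res2 <- loocvGridSearch(tab2, g, seed = 1L, returnArtifacts = TRUE)
  f1 <- res1$artifacts[[which(vapply(res1$artifacts, `[[`, "", "heldOut")
                              == "spec03")]]
  f2 <- res2$artifacts[[which(vapply(res2$artifacts, `[[`, "", "heldOut")
                              == "spec03")]]
  expect_identical(f1$stats, f2$stats)
  expect_identical(f1$rankings, f2$rankings)
})

test_that("trainFinal honors the combination and emits probabilities", {
  tab <- makeFakeTable(nSpec = 4L, nPerSpec = 20L)
  model <- trainFinal(tab, list(classifier = "SVM", selector = "MRMR",
                                nFeatures = 4L), seed = 1L)
  expect_length(model@features, 4L)
  expect_identical(model@classifier, "SVM")
  p <- optomics:::modelProbabilities(model, tab)
  expect_true(all(p >= 0 & p <= 1))
  model2 <- trainFinal(tab, list(classifier = "SVM", selector = "MRMR",
                                 nFeatures = 4L), seed = 1L)
  expect_identical(model2@features, model@features)
})
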