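# Shared fixtures, built in code and cached across test files.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtureCache[[name]]))
    .fixtureCache[[name]] <- force(expr)
  .fixtureCache[[name]]
}

# a small scene (160 x 160 px) with the default texture models
tinyScene <- function(seed = 7L, ...) {
  sceneSpec(imageHeightPx = 160L, imageWidthPx = 160L,
            tissueGeometry = list(centerFrac = c(0.5, 0.5),
                                  radiiPx = c(62, 52), roughness = 0.08,
                                  nHarmonics = 5L),
            tumorGeometry = list(centerOffsetFrac = c(0.1, -0.08),
                                 radiiPx = c(26, 21), roughness = 0.15,
                                 nHarmonics = 5L),
            mucosaBandWidthPx = 4L, seed = seed, ...)
}

defaultSpecimen <- function() {
  fixture("defaultSpecimen", generateSpecimen(sceneSpec(seed = 42L)))
}

defaultStandardized <- function() {
  fixture("defaultStandardized", preprocessSpecimen(defaultSpecimen()))
}

tinySpecimen <- function() {
  fixture("tinySpecimen", generateSpecimen(tinyScene()))
}

tinyStandardized <- function() {
  fixture("tinyStandardized", preprocessSpecimen(tinySpecimen()))
}

# integer test patches (levels already in 1..ng) for the texture oracles
oraclePatches <- function() {
  set.seed(11)
  list(
    constant = list(lev = matrix(2L, 4, 4), ng = 2L),
    binaryChecker = list(
      lev = matrix(rep_len(c(1L, 2L), 25), 5, 5), ng = 2L),
    smallRandom4 = list(
      lev = matrix(sample.int(4L, 30, replace = TRUE), 5, 6), ng = 4L),
    random8 = list(
      lev = matrix(sample.int(8L, 36, replace = TRUE), 6, 6), ng = 8L),
    singleOutlier = list(
      lev = {
        m <- matrix(1L, 6, 6); m[3, 4] <- 3L; m
      }, ng = 3L),
    rows = list(
      lev = matrix(rep(1:6, each = 6), 6, 6, byrow = TRUE), ng = 6L))
}

# a synthetic feature table built directly (samples from several specimens,
# a handful of features, controllable informativeness)
makeFakeTable <- function(nSpec = 4L, nPerSpec = 25L, nFeat = 12L,
                          seed = 3L) {
  set.seed(seed)
  n <- nSpec * nPerSpec
  sid <- rep(sprintf("spec%02d", seq_len(nSpec)), each = nPerSpec)
  y <- rep_len(c(0L, 1L), n)
  X <- matrix(rnorm(n * nFeat), n, nFeat)
  # first three features informative at decreasing strength
  X[, 1] <- X[, 1] + 2.5 * y
  X[, 2] <- X[, 2] + 1.5 * y
  X[, 3] <- X[, 3] + 0.8 * y
  colnames(X) <- sprintf("feat%02d", seq_len(nFeat))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(optomics = t(X)),
    colData = S4Vectors::DataFrame(
      specimenId = sid, centerRow = seq_len(n), centerCol = seq_len(n),
      scaleMm = rep(1.8, n),
      label = ifelse(y == 1L, "malignant", "non_malignant")),
    metadata = list(standardized = FALSE))
}

# a small trained model plus a matching scored table, for probability-map
# tests
smallModelAndTable <- function() {
  fixture("smallModelAndTable", {
    tab <- makeFakeTable(nSpec = 2L, nPerSpec = 30L, nFeat = 6L, seed = 9L)
    model <- trainFinal(tab, list(classifier = "DT", selector = "PRCC",
                                  nFeatures = 3L), seed = 5L)
    list(model = model, table = tab)
  })
}
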