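# End-to-end orchestration: simulate a cohort, preprocess, partition,
# sample patches, extract features, run the cross-validated grid search,
# train both methods, evaluate them on the held-out specimens and
# (optionally) produce multi-scale probability maps.

#' Assemble a pipeline configuration
#'
#' Defaults describe the full study conditions (24 specimens in 3 dose
#' groups, area-proportional patch density, the 15-filter feature set and
#' the 980-combination grid). Tests and quick experiments pass reduced
#' settings (fixed per-class patch counts, a filter subset, a small grid).
#'
#' @param seed pipeline master seed; all stage seeds derive from it.
#' @param nPerGroup specimens per dose group.
#' @param baseSpec template [SceneSpec-class] for the generator.
#' @param doseScales per-group brightness multipliers.
#' @param trainFraction per-group training fraction (default 0.75).
#' @param patch [PatchSpec-class] template for sampling.
#' @param features [featureConfig()] list.
#' @param grid [gridSpec()].
#' @param scalesMm patch scales for probability maps.
#' @param makeMaps build probability maps for test specimens (slow).
#' @param outdir optional output directory for artifacts.
#' @return named list configuration.
#' @export
pipelineConfig <- function(seed = 1L, nPerGroup = 8L,
                           baseSpec = sceneSpec(),
                           doseScales = c(0.5, 1, 1.6),
                           trainFraction = 0.75,
                           patch = patchSpec(),
                           features = featureConfig(),
                           grid = gridSpec(),
                           scalesMm = c(1.8, 1.4, 0.9),
                           makeMaps = FALSE, outdir = NULL) {
  list(seed = as.integer(seed), nPerGroup = as.integer(nPerGroup),
       baseSpec = baseSpec, doseScales = doseScales,
       trainFraction = trainFraction, patch = patch, features = features,
       grid = grid, scalesMm = scalesMm, makeMaps = makeMaps,
       outdir = outdir)
}

#' Reduced demo configuration
#'
#' The full study conditions (area-proportional patch density, 15 filters,
#' 980-combination grid) are expensive; this configuration keeps the cohort
#' design (24 specimens, 8 per dose group, 75/25 split) but fixes 30
#' patches per class per training specimen (30 per testing specimen), uses
#' the 92 base features plus 4 filters (two wavelet sub-bands, the finest
#' LoG scale and the gradient magnitude), and restricts the grid to
#' SVM x MRMR x \{10, 25\} features. It reproduces the headline comparison
#' in minutes on one CPU.
#'
#' @param seed pipeline master seed.
#' @return a [pipelineConfig()] list.
#' @export
smokeConfig <- function(seed = 1L) {
  pipelineConfig(
    seed = seed,
    patch = patchSpec(nPerClassTarget = 30),
    features = featureConfig(filters = c("wavelet-LL", "wavelet-HH",
                                         "log-sigma-0.25", "gradient")),
    grid = gridSpec(classifiers = "SVM", selectors = "MRMR",
                    featureCounts = c(10L, 25L)))
}

samplePatchTable <- function(specimens, images, ids, patch, features,
                             training = TRUE) {
  sets <- list()
  for (sid in ids) {
    k <- match(sid, vapply(specimens, specimenId, ""))
    ps <- if (training)
      sampleTrainingPatches(images[[k]], specimens[[k]]@mask, patch)
    else sampleTestingPatches(images[[k]], specimens[[k]]@mask, patch)
    if (length(ps) > 0) sets[[length(sets) + 1L]] <- ps
  }
  buildFeatureTable(combinePatchSets(sets), features)
}

#' Run the full two-method demo experiment
#'
#' Simulate cohort, preprocess, partition per dose group, sample training
#' patches under the containment rule, extract optomic features, run the
#' specimen-level LOOCV grid search, train the winning combination and the
#' intensity-thresholding baseline on the training set, and evaluate both
#' on the test specimens (patch level for optomics, ROI pixel level for
#' thresholding). Deterministic for a given configuration.
#'
#' @param config a [pipelineConfig()].
#' @return list with elements `partition`, `ocpModel`, `gridResult`,
#'   `model`, `reportOptomics`, `reportThresholding`, `comparison`, and
#'   `maps` (NULL unless `makeMaps`).
#' @export
runDemo <- function(config = pipelineConfig()) {
  seed <- config$seed
  cohort <- generateCohort(config$nPerGroup, config$baseSpec, seed,
                           config$doseScales)
  images <- lapply(cohort, preprocessSpecimen)
  ids <- vapply(cohort, specimenId, "")
  part <- partitionCohort(cohort, config$trainFraction, seed + 1L)

  patch <- config$patch
  patch@seed <- as.integer(seed + 11L)
  trainTable <- samplePatchTable(cohort, images, part$train, patch,
                                 config$features, training = TRUE)
  testTable <- samplePatchTable(cohort, images, part$test, patch,
                                config$features, training = FALSE)

  # thresholding baseline: OCP on all training ROI pixels
  trIdx <- match(part$train, ids)
  pix <- unlist(lapply(trIdx, function(k) {
    roi <- cohort[[k]]@mask@labels >= 1L
    images[[k]]@pixels[roi]
  }))
  lab <- unlist(lapply(trIdx, function(k) {
    roi <- cohort[[k]]@mask@labels >= 1L
    cohort[[k]]@mask@labels[roi] == 2L
  }))
  ocpModel <- fitOcp(pix, lab)

  gridResult <- loocvGridSearch(trainTable, config$grid, seed = seed + 21L)
  model <- trainFinal(trainTable, gridResult$best, seed = seed + 31L)

  reportOptomics <- evaluateOptomics(model, testTable)
  teIdx <- match(part$test, ids)
  reportThresholding <- evaluateThresholding(
    ocpModel, images[teIdx], lapply(cohort[teIdx], function(s) s@mask))
  comparison <- pairedCompare(reportOptomics, reportThresholding)

  maps <- NULL
  if (isTRUE(config$makeMaps)) {
    models <- lapply(config$scalesMm, function(sc) {
      psc <- patchSpec(sideMm = sc,
                       pixelSizeMm = config$features$pixelSizeMm,
                       minInsideFraction = patch@minInsideFraction,
                       nPerClassTarget = patch@nPerClassTarget,
                       densityPerMm2 = patch@densityPerMm2,
                       seed = patch@seed)
      tab <- samplePatchTable(cohort, images, part$train, psc,
                              config$features, training = TRUE)
      trainFinal(tab, gridResult$best, seed = seed + 31L)
    })
    maps <- lapply(teIdx, function(k) {
      probabilityMap(models, images[[k]], cohort[[k]]@mask,
                     config$scalesMm, patch, config$features)
    })
    names(maps) <- part$test
  }

  out <- list(partition = part, ocpModel = ocpModel,
              gridResult = gridResult, model = model,
              reportOptomics = reportOptomics,
              reportThresholding = reportThresholding,
              comparison = comparison, maps = maps)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    writeEvalReport(reportOptomics,
                    file.path(config$outdir, "report_optomics.json"))
    writeEvalReport(reportThresholding,
                    file.path(config$outdir, "report_thresholding.json"))
    write.csv(comparison, file.path(config$outdir, "paired_tests.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, best = gridResult$best, ocp = ocpModel@ocp),
      file.path(config$outdir, "run_summary.json"), auto_unbox = TRUE,
      digits = NA)
  }
  out
}
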