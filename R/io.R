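# Plain-file I/O: single-channel TIFF images (32-bit float, with a JSON
# sidecar carrying metadata and the intensity scale factor, since TIFF
# storage here is defined on [0,1]), integer label masks as 8-bit TIFF, and
# CSV patch manifests.

#' Write a specimen image as 32-bit float TIFF plus JSON sidecar
#'
#' Intensities are stored divided by a scale factor (the image maximum when
#' above 1) recorded in the sidecar together with the image metadata.
#'
#' @param image a [SpecimenImage-class].
#' @param path output path (".tif"); the sidecar is `<path>.json`.
#' @return invisibly, the path.
#' @export
writeSpecimenTiff <- function(image, path) {
  scale <- max(max(image@pixels), 1)
  tiff::writeTIFF(image@pixels / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- list(scale = scale, pixelSizeMm = image@pixelSizeMm,
               specimenId = image@specimenId, doseGroup = image@doseGroup,
               calibrationValue = image@calibrationValue,
               isStandardized = image@isStandardized)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a specimen image written by [writeSpecimenTiff()]
#'
#' @param path TIFF path with a `<path>.json` sidecar.
#' @return A [SpecimenImage-class].
#' @export
readSpecimenTiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * meta$scale
  SpecimenImage(px, pixelSizeMm = meta$pixelSizeMm,
                specimenId = meta$specimenId,
                doseGroup = as.integer(meta$doseGroup),
                calibrationValue = meta$calibrationValue,
                isStandardized = isTRUE(meta$isStandardized))
}

#' Write a label mask as 8-bit TIFF (labels 0/1/2)
#' @param mask a [LabelMask-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMaskTiff <- function(mask, path) {
  tiff::writeTIFF(mask@labels / 255, path, bits.per.sample = 8L,
                  reduce = FALSE)
  invisible(path)
}

#' Read a label mask written by [writeMaskTiff()]
#' @param path TIFF path.
#' @return A [LabelMask-class].
#' @export
readMaskTiff <- function(path) {
  LabelMask(matrix(as.integer(round(tiff::readTIFF(path) * 255)),
                   nrow = dim(tiff::readTIFF(path))[1]))
}

#' Write a patch manifest as CSV
#'
#' Columns: specimenId, centerRow, centerCol, scaleMm, label.
#'
#' @param patches a [PatchSet-class].
#' @param path CSV output path.
#' @return invisibly, the path.
#' @export
writePatchManifest <- function(patches, path) {
  write.csv(patchInfo(patches), path, row.names = FALSE)
  invisible(path)
}

#' Write a feature table as CSV (one row per patch)
#'
#' The provenance columns precede the feature columns; feature names form a
#' stable header.
#'
#' @param table feature SummarizedExperiment.
#' @param path CSV output path.
#' @return invisibly, the path.
#' @export
writeFeatureCsv <- function(table, path) {
  info <- as.data.frame(SummarizedExperiment::colData(table))
  X <- t(SummarizedExperiment::assay(table, "optomics"))
  write.csv(cbind(info, as.data.frame(X, check.names = FALSE)), path,
            row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report as JSON
#' @param report an [EvalReport-class].
#' @param path JSON output path.
#' @return invisibly, the path.
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(list(method = report@method,
                            perSpecimen = report@perSpecimen,
                            aggregate = as.list(report@aggregate)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
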