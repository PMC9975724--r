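# Image filter bank applied to patches before texture feature extraction.
# The default bank has 15 members: 4 undecimated Haar wavelet sub-bands,
# 5 Laplacian-of-Gaussian scales, and 6 intensity/derivative transforms.
# Every filter output is linearly rescaled back to the input patch's
# intensity range so that discretization operates on a comparable scale.

shiftRow <- function(x, d) {
  n <- nrow(x)
  idx <- pmin(pmax(seq_len(n) + d, 1L), n)
  x[idx, , drop = FALSE]
}

shiftCol <- function(x, d) {
  n <- ncol(x)
  idx <- pmin(pmax(seq_len(n) + d, 1L), n)
  x[, idx, drop = FALSE]
}

haarLo <- function(x, dim) {
  if (dim == 1L) (x + shiftRow(x, 1L)) / 2 else (x + shiftCol(x, 1L)) / 2
}

haarHi <- function(x, dim) {
  if (dim == 1L) (x - shiftRow(x, 1L)) / 2 else (x - shiftCol(x, 1L)) / 2
}

logFilter <- function(x, sigmaPx) {
  sm <- smoothGaussian(x, sigmaPx)
  shiftRow(sm, 1L) + shiftRow(sm, -1L) + shiftCol(sm, 1L) +
    shiftCol(sm, -1L) - 4 * sm
}

gradientMagnitude <- function(x) {
  gx <- (shiftCol(x, 1L) - shiftCol(x, -1L)) / 2
  gy <- (shiftRow(x, 1L) - shiftRow(x, -1L)) / 2
  sqrt(gx^2 + gy^2)
}

discreteLaplacian <- function(x) {
  shiftRow(x, 1L) + shiftRow(x, -1L) + shiftCol(x, 1L) + shiftCol(x, -1L) -
    4 * x
}

# Degenerate ranges (constant input or constant response) are passed
# through unchanged: a flat sub-band of a flat patch stays zero.
rescaleToRange <- function(y, lo, hi) {
  ymin <- min(y); ymax <- max(y)
  if (hi == lo || ymax == ymin) return(y)
  (y - ymin) / (ymax - ymin) * (hi - lo) + lo
}

#' Names of the default 15-member filter bank
#'
#' Four stationary Haar wavelet sub-bands (`wavelet-LL/LH/HL/HH`; first
#' letter = row filter, second = column filter), five Laplacian-of-Gaussian
#' scales (`log-sigma-<mm>` for sigma in 0.25, 0.5, 0.75, 1.0, 1.25 mm,
#' converted to pixels via the pixel size), and six intensity/derivative
#' transforms (`square`, `squareroot`, `logarithm`, `exponential`,
#' `gradient`, `laplacian`).
#'
#' @return character vector of length 15.
#' @export
defaultFilterBank <- function() {
  c("wavelet-LL", "wavelet-LH", "wavelet-HL", "wavelet-HH",
    "log-sigma-0.25", "log-sigma-0.5", "log-sigma-0.75", "log-sigma-1",
    "log-sigma-1.25", "square", "squareroot", "logarithm", "exponential",
    "gradient", "laplacian")
}

#' Apply one named filter to a patch
#'
#' @param x numeric patch matrix (values in \[0,1\]).
#' @param name filter name, one of [defaultFilterBank()].
#' @param pixelSizeMm pixel size, used to convert LoG sigma from mm to px.
#' @return filtered matrix of the same size, rescaled to the input's
#'   intensity range.
#' @export
applyFilter <- function(x, name, pixelSizeMm = 0.042) {
  lo <- min(x); hi <- max(x)
  y <- switch(name,
    "wavelet-LL" = haarLo(haarLo(x, 1L), 2L),
    "wavelet-LH" = haarHi(haarLo(x, 1L), 2L),
    "wavelet-HL" = haarLo(haarHi(x, 1L), 2L),
    "wavelet-HH" = haarHi(haarHi(x, 1L), 2L),
    "square" = x^2,
    "squareroot" = sqrt(pmax(x, 0)),
    "logarithm" = log1p(pmax(x, 0)),
    "exponential" = exp(x),
    "gradient" = gradientMagnitude(x),
    "laplacian" = discreteLaplacian(x),
    {
      if (!grepl("^log-sigma-", name)) stop("unknown filter: ", name)
      sigmaMm <- as.numeric(sub("^log-sigma-", "", name))
      logFilter(x, sigmaMm / pixelSizeMm)
    })
  rescaleToRange(y, lo, hi)
}

#' Apply a filter bank to a patch
#'
#' @param x numeric patch matrix.
#' @param bank character vector of filter names (default the 15-member bank).
#' @param pixelSizeMm pixel size in mm.
#' @return named list of filtered matrices, same size as the input.
#' @export
applyFilterBank <- function(x, bank = defaultFilterBank(),
                            pixelSizeMm = 0.042) {
  if (min(dim(x)) < 3L) stop("patch smaller than the filter support")
  out <- lapply(bank, function(nm) applyFilter(x, nm, pixelSizeMm))
  names(out) <- bank
  out
}
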