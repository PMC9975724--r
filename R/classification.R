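# Training and evaluation of the two competing methods: the optomics
# classifier grid (specimen-level leave-one-out cross-validation over
# classifier x selector x feature-count combinations) and the
# fluorescence-intensity thresholding baseline (pixel-level ROC sweep for
# the optimum cutoff point). Both are scored per test specimen with
# accuracy, false positive rate and false negative rate, and compared with
# a paired two-sided t-test.

#' Hyperparameter grid specification
#'
#' The default grid is 7 classifiers x 7 selectors x 20 feature counts
#' (5, 10, ..., 100) = 980 combinations.
#'
#' @param classifiers subset of `c("RF","kNN","DT","SVM","BST","BY","DA")`.
#' @param selectors subset of
#'   `c("MRMR","FSCR","CHSQ","GINI","MIM","SRCC","PRCC")`.
#' @param featureCounts integer vector of feature-count options.
#' @param sdTolerance parsimony tolerance in standard deviations (default
#'   1.5): the winner is the fewest-feature combination whose mean CV
#'   accuracy is within `sdTolerance` fold-accuracy SDs of the maximum.
#' @return list with class "gridSpec".
#' @export
gridSpec <- function(classifiers = classifierTags,
                     selectors = selectorTags,
                     featureCounts = seq(5L, 100L, by = 5L),
                     sdTolerance = 1.5) {
  classifiers <- match.arg(classifiers, classifierTags, several.ok = TRUE)
  selectors <- match.arg(selectors, selectorTags, several.ok = TRUE)
  structure(list(classifiers = classifiers, selectors = selectors,
                 featureCounts = as.integer(featureCounts),
                 sdTolerance = sdTolerance), class = "gridSpec")
}

#' Number of hyperparameter combinations in a grid
#' @param grid a [gridSpec()].
#' @return integer combination count.
#' @export
gridSize <- function(grid) {
  length(grid$classifiers) * length(grid$selectors) *
    length(grid$featureCounts)
}

#' Partition a cohort into training/testing specimens per dose group
#'
#' Each dose group is split at random with the given training fraction and
#' the per-group splits are aggregated; with 8 specimens per group and a
#' 0.75 fraction this yields 18 training and 6 testing specimens.
#'
#' @param specimens list of [SyntheticSpecimen-class] (or any objects with
#'   [specimenId()] and [doseGroup()] methods).
#' @param trainFraction fraction of each group assigned to training.
#' @param seed RNG seed for the random split.
#' @return list(train, test) of specimen id character vectors.
#' @export
partitionCohort <- function(specimens, trainFraction = 0.75, seed = 1L) {
  ids <- vapply(specimens, specimenId, "")
  groups <- vapply(specimens, doseGroup, 0L)
  stopifnot(!anyDuplicated(ids))
  set.seed(seed)
  train <- character(0); test <- character(0)
  for (g in sort(unique(groups))) {
    gid <- ids[groups == g]
    if (length(gid) < 2L)
      stop("dose group ", g, " has fewer than 2 specimens")
    nTrain <- round(trainFraction * length(gid))
    if (nTrain >= length(gid) || nTrain < 1L)
      stop("trainFraction leaves an empty training or testing set")
    pick <- sample(gid, nTrain)
    train <- c(train, pick)
    test <- c(test, setdiff(gid, pick))
  }
  list(train = train, test = test)
}

#' Fit the optimum cutoff point (OCP) for intensity thresholding
#'
#' Sweeps candidate thresholds at every unique intensity, at the midpoints
#' between consecutive unique intensities, and one step above the maximum
#' (the all-negative rule). A pixel is classified tumor when its intensity
#' is greater than or equal to the threshold; the OCP is the threshold
#' maximizing training accuracy, ties resolved toward the lowest candidate.
#'
#' @param intensities numeric vector of training pixel intensities.
#' @param labels binary vector (1/TRUE = tumor).
#' @return A [ThresholdModel-class].
#' @export
fitOcp <- function(intensities, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to fit the OCP")
  u <- sort(unique(intensities))
  cand <- sort(unique(c(u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
                        u[length(u)] + 1)))
  posSorted <- sort(intensities[labels])
  negSorted <- sort(intensities[!labels])
  nPos <- length(posSorted); nNeg <- length(negSorted)
  # number of tumor pixels >= t and normal pixels < t, per candidate
  tp <- nPos - findInterval(cand, posSorted, left.open = TRUE)
  tn <- findInterval(cand, negSorted, left.open = TRUE)
  acc <- (tp + tn) / (nPos + nNeg)
  best <- which.max(acc)  # which.max returns the first (lowest) maximizer
  new("ThresholdModel", ocp = cand[best], trainAccuracy = acc[best])
}

# Samples-x-features matrix and binary labels of the labeled patches in a
# feature table.
tableXY <- function(table) {
  info <- as.data.frame(SummarizedExperiment::colData(table))
  keep <- info$label %in% c("malignant", "non_malignant")
  X <- t(SummarizedExperiment::assay(table, "optomics")[, keep, drop = FALSE])
  list(X = X, y = as.integer(info$label[keep] == "malignant"),
       specimenId = info$specimenId[keep])
}

#' Specimen-level leave-one-out cross-validated grid search
#'
#' For each fold, all patches of one training specimen are held out;
#' Z-score statistics and feature rankings are recomputed on the in-fold
#' specimens only, so no information from the held-out specimen leaks into
#' selection or standardization. Validation accuracy is the patch accuracy
#' on the held-out specimen; each combination's score is its mean over
#' folds. The winner is chosen by the parsimony rule: among combinations
#' whose mean accuracy is within `sdTolerance` fold-accuracy standard
#' deviations of the maximum, pick the fewest features (remaining ties:
#' higher mean, then tag order).
#'
#' @param table an unstandardized labeled feature table
#'   ([buildFeatureTable()]) of all training specimens.
#' @param grid a [gridSpec()].
#' @param seed integer seed for stochastic classifiers.
#' @param returnArtifacts if TRUE, also return each fold's Z-score
#'   statistics and rankings (used to verify the no-leakage property).
#' @return list with elements `best` (classifier, selector, nFeatures),
#'   `cvMean` (classifier x selector x K array), `foldAccuracy`
#'   (fold x classifier x selector x K), `accThreshold`, and optionally
#'   `artifacts`.
#' @export
loocvGridSearch <- function(table, grid = gridSpec(), seed = 1L,
                            returnArtifacts = FALSE) {
  if (isTRUE(S4Vectors::metadata(table)$standardized))
    stop("supply the raw (unstandardized) feature table")
  dat <- tableXY(table)
  specimens <- sort(unique(dat$specimenId))
  nFold <- length(specimens)
  if (nFold < 2L) stop("at least 2 training specimens required")
  Ks <- grid$featureCounts
  Kmax <- max(Ks)
  acc <- array(NA_real_,
               c(nFold, length(grid$classifiers), length(grid$selectors),
                 length(Ks)),
               dimnames = list(specimens, grid$classifiers, grid$selectors,
                               Ks))
  artifacts <- if (returnArtifacts) vector("list", nFold) else NULL
  for (f in seq_len(nFold)) {
    held <- specimens[f]
    inFold <- dat$specimenId != held
    if (!any(inFold) || !any(!inFold)) stop("empty fold")
    Xtr <- dat$X[inFold, , drop = FALSE]
    ytr <- dat$y[inFold]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    zero <- !is.finite(sdv) | sdv == 0
    scale1 <- ifelse(zero, 1, sdv)
    Ztr <- sweep(sweep(Xtr, 2, mu), 2, scale1, "/")
    Ztr[, zero] <- 0
    Zva <- sweep(sweep(dat$X[!inFold, , drop = FALSE], 2, mu), 2, scale1,
                 "/")
    Zva[, zero] <- 0
    yva <- dat$y[!inFold]
    foldRankings <- list()
    for (s in seq_along(grid$selectors)) {
      ranking <- rankFeatures(Ztr, ytr, grid$selectors[s], Kmax)
      foldRankings[[grid$selectors[s]]] <- ranking
      for (cl in seq_along(grid$classifiers)) {
        for (k in seq_along(Ks)) {
          feats <- ranking$feature[seq_len(Ks[k])]
          model <- fitClassifier(grid$classifiers[cl],
                                 Ztr[, feats, drop = FALSE], ytr,
                                 seed = seed + f)
          p <- predictMalignantProb(model, Zva[, feats, drop = FALSE])
          acc[f, cl, s, k] <- mean((p >= 0.5) == (yva == 1L))
        }
      }
    }
    if (returnArtifacts)
      artifacts[[f]] <- list(heldOut = held,
                             stats = data.frame(feature = colnames(dat$X),
                                                mu = mu, sd = sdv),
                             rankings = foldRankings)
  }
  cvMean <- apply(acc, c(2, 3, 4), mean)
  idxMax <- which(cvMean == max(cvMean), arr.ind = TRUE)
  idxMax <- idxMax[order(idxMax[, 3], idxMax[, 1], idxMax[, 2]), ,
                   drop = FALSE][1, ]
  sdMax <- stats::sd(acc[, idxMax[1], idxMax[2], idxMax[3]])
  if (!is.finite(sdMax)) sdMax <- 0
  thr <- max(cvMean) - grid$sdTolerance * sdMax
  eligible <- which(cvMean >= thr, arr.ind = TRUE)
  kBest <- min(eligible[, 3])
  eligible <- eligible[eligible[, 3] == kBest, , drop = FALSE]
  means <- cvMean[eligible[, c(1, 2, 3), drop = FALSE]]
  eligible <- eligible[order(-means, eligible[, 1], eligible[, 2]), ,
                       drop = FALSE][1, ]
  best <- list(classifier = grid$classifiers[eligible[1]],
               selector = grid$selectors[eligible[2]],
               nFeatures = Ks[eligible[3]])
  out <- list(best = best, cvMean = cvMean, foldAccuracy = acc,
              accThreshold = thr,
              bestMeanAccuracy = cvMean[eligible[1], eligible[2],
                                        eligible[3]],
              maxMeanAccuracy = max(cvMean), sdMax = sdMax)
  if (returnArtifacts) out$artifacts <- artifacts
  out
}

#' Train the final optomics model for one hyperparameter combination
#'
#' Z-score statistics and the feature ranking are computed on the full
#' training table; the classifier is fitted on the selected standardized
#' features.
#'
#' @param table unstandardized labeled training feature table.
#' @param combo list(classifier, selector, nFeatures), e.g. the `best`
#'   element of [loocvGridSearch()].
#' @param seed integer seed for stochastic classifiers.
#' @return An [OptomicsModel-class].
#' @export
trainFinal <- function(table, combo, seed = 1L) {
  dat <- tableXY(table)
  mu <- colMeans(dat$X)
  sdv <- apply(dat$X, 2, stats::sd)
  zero <- !is.finite(sdv) | sdv == 0
  Z <- sweep(sweep(dat$X, 2, mu), 2, ifelse(zero, 1, sdv), "/")
  Z[, zero] <- 0
  ranking <- rankFeatures(Z, dat$y, combo$selector, combo$nFeatures)
  feats <- ranking$feature
  fit <- fitClassifier(combo$classifier, Z[, feats, drop = FALSE], dat$y,
                       seed = seed)
  scale <- unique(as.data.frame(
    SummarizedExperiment::colData(table))$scaleMm)
  new("OptomicsModel", classifier = combo$classifier,
      selector = combo$selector, features = feats,
      centerStats = data.frame(feature = colnames(dat$X), mu = mu, sd = sdv,
                               stringsAsFactors = FALSE),
      fit = fit, scaleMm = scale[1])
}

# Standardize a feature table with a model's training statistics and return
# malignancy probabilities for all its patches.
modelProbabilities <- function(model, table) {
  X <- t(SummarizedExperiment::assay(table, "optomics"))
  st <- model@centerStats
  st <- st[match(colnames(X), st$feature), ]
  zero <- !is.finite(st$sd) | st$sd == 0
  Z <- sweep(sweep(X, 2, st$mu), 2, ifelse(zero, 1, st$sd), "/")
  Z[, zero] <- 0
  predictMalignantProb(model@fit, Z[, model@features, drop = FALSE])
}

confusionMetrics <- function(tp, fn, fp, tn) {
  c(accuracy = (tp + tn) / (tp + fn + fp + tn),
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    fnr = if (fn + tp > 0) fn / (fn + tp) else NA_real_)
}

makeEvalReport <- function(method, rows) {
  perSpecimen <- do.call(rbind, rows)
  rownames(perSpecimen) <- NULL
  agg <- c(accuracy = mean(perSpecimen$accuracy, na.rm = TRUE),
           fpr = mean(perSpecimen$fpr, na.rm = TRUE),
           fnr = mean(perSpecimen$fnr, na.rm = TRUE))
  new("EvalReport", method = method, perSpecimen = perSpecimen,
      aggregate = agg)
}

#' Evaluate an optomics model on a labeled test feature table
#'
#' Predictions are patch-level (probability >= 0.5 means malignant);
#' metrics are computed per test specimen over its labeled patches and
#' averaged. Specimens with no labeled patches are excluded with a warning.
#'
#' @param model an [OptomicsModel-class].
#' @param table feature table of test patches (labeled + unlabeled).
#' @return An [EvalReport-class].
#' @export
evaluateOptomics <- function(model, table) {
  info <- as.data.frame(SummarizedExperiment::colData(table))
  p <- modelProbabilities(model, table)
  rows <- list()
  for (sid in unique(info$specimenId)) {
    sel <- info$specimenId == sid &
      info$label %in% c("malignant", "non_malignant")
    if (!any(sel)) {
      warning("specimen ", sid, " has no labeled patches; excluded")
      next
    }
    truth <- info$label[sel] == "malignant"
    pred <- p[sel] >= 0.5
    tp <- sum(pred & truth); fn <- sum(!pred & truth)
    fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
    m <- confusionMetrics(tp, fn, fp, tn)
    rows[[length(rows) + 1L]] <-
      data.frame(specimenId = sid, n = sum(sel), tp = tp, fn = fn, fp = fp,
                 tn = tn, accuracy = m["accuracy"], fpr = m["fpr"],
                 fnr = m["fnr"], stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no labeled test patches")
  makeEvalReport("optomics", rows)
}

#' Evaluate the thresholding baseline on test specimens
#'
#' Pixel-level evaluation restricted to ROI pixels: tumor-ROI pixels at or
#' above the OCP are true positives, below are false negatives; normal-ROI
#' pixels at or above the OCP are false positives, below true negatives.
#'
#' @param model a [ThresholdModel-class].
#' @param images list of standardized [SpecimenImage-class] test images.
#' @param masks list of matching [LabelMask-class] objects.
#' @return An [EvalReport-class].
#' @export
evaluateThresholding <- function(model, images, masks) {
  stopifnot(length(images) == length(masks))
  rows <- list()
  for (k in seq_along(images)) {
    img <- images[[k]]; lab <- masks[[k]]@labels
    roi <- lab >= 1L
    if (!any(roi)) {
      warning("specimen ", img@specimenId, " has no ROI pixels; excluded")
      next
    }
    x <- img@pixels[roi]
    truth <- lab[roi] == 2L
    pred <- x >= model@ocp
    tp <- sum(pred & truth); fn <- sum(!pred & truth)
    fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
    m <- confusionMetrics(tp, fn, fp, tn)
    rows[[length(rows) + 1L]] <-
      data.frame(specimenId = img@specimenId, n = sum(roi), tp = tp,
                 fn = fn, fp = fp, tn = tn, accuracy = m["accuracy"],
                 fpr = m["fpr"], fnr = m["fnr"], stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no evaluable test specimens")
  makeEvalReport("thresholding", rows)
}

#' Paired two-sided t-test comparison of two evaluation reports
#'
#' Compares per-specimen accuracy, FPR and FNR between two reports on the
#' same specimens. Conventions: all-zero differences give p = 1; zero
#' variance with a nonzero mean difference gives p = 0 (flagged as below
#' machine precision).
#'
#' @param reportA,reportB [EvalReport-class] objects over identical
#'   specimen sets.
#' @return data.frame(metric, meanA, meanB, meanDiff, t, df, p).
#' @export
pairedCompare <- function(reportA, reportB) {
  a <- reportA@perSpecimen
  b <- reportB@perSpecimen
  if (!setequal(a$specimenId, b$specimenId))
    stop("reports cover different specimen sets")
  b <- b[match(a$specimenId, b$specimenId), ]
  out <- lapply(c("accuracy", "fpr", "fnr"), function(metric) {
    d <- a[[metric]] - b[[metric]]
    d <- d[is.finite(d)]
    n <- length(d)
    if (n < 2L) stop("need at least 2 paired specimens")
    sdd <- stats::sd(d)
    if (sdd == 0) {
      tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- mean(d) / (sdd / sqrt(n))
      p <- 2 * pt(-abs(tt), df = n - 1)
    }
    data.frame(metric = metric, meanA = mean(a[[metric]], na.rm = TRUE),
               meanB = mean(b[[metric]], na.rm = TRUE), meanDiff = mean(d),
               t = tt, df = n - 1, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
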