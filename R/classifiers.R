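# Uniform wrappers around the seven classifier backends. Each wrapper fits
# on a samples x features matrix with binary labels (1 = malignant) and
# returns an object whose predictions are class probabilities in [0,1].
# Backend settings are fixed: SVM uses a radial-basis kernel with internal
# probability calibration; kNN uses k = 5; RF grows 100 trees; boosting is
# 50 rounds of depth-3 gradient-boosted trees; DT/BY/DA use library
# defaults. Stochastic backends are seeded for reproducibility.

classifierTags <- c("RF", "kNN", "DT", "SVM", "BST", "BY", "DA")
selectorTags <- c("MRMR", "FSCR", "CHSQ", "GINI", "MIM", "SRCC", "PRCC")

#' Fit one of the seven classifiers
#'
#' @param type classifier tag: "RF", "kNN", "DT", "SVM", "BST", "BY", "DA".
#' @param X numeric samples x features matrix (standardized features).
#' @param y binary labels (0/1 or logical; 1 = malignant).
#' @param seed integer seed for stochastic backends.
#' @return opaque classifier object for [predictMalignantProb()].
#' @export
fitClassifier <- function(type, X, y, seed = 1L) {
  type <- match.arg(type, classifierTags)
  y <- as.integer(y)
  yf <- factor(y, levels = c(0L, 1L))
  X <- as.matrix(X)
  set.seed(seed)
  fit <- switch(type,
    SVM = e1071::svm(x = X, y = yf, kernel = "radial", probability = TRUE),
    RF = randomForest::randomForest(x = X, y = yf, ntree = 100),
    DT = {
      df <- data.frame(X, .y = yf, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    kNN = list(X = X, y = yf, k = 5L),
    BST = xgboost::xgboost(data = X, label = y, nrounds = 50, max_depth = 3,
                           eta = 0.3, objective = "binary:logistic",
                           verbose = 0, nthread = 1),
    BY = e1071::naiveBayes(x = X, y = yf),
    DA = tryCatch(MASS::lda(X, grouping = yf),
                  error = function(e) list(prior = mean(y))))
  structure(list(type = type, fit = fit, features = colnames(X)),
            class = "optomicsClassifier")
}

#' Predict malignancy probability from a fitted classifier
#'
#' @param model object from [fitClassifier()].
#' @param X samples x features matrix with the model's feature columns.
#' @return numeric vector of probabilities in \[0,1\].
#' @export
predictMalignantProb <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  fit <- model$fit
  p <- switch(model$type,
    SVM = {
      pr <- predict(fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    RF = predict(fit, X, type = "prob")[, "1"],
    DT = predict(fit, data.frame(X, check.names = FALSE),
                 type = "prob")[, "1"],
    kNN = {
      pr <- class::knn(fit$X, X, fit$y, k = fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    BST = predict(fit, X),
    BY = {
      raw <- predict(fit, X, type = "raw")
      raw[, "1"]
    },
    DA = {
      if (is.list(fit) && !inherits(fit, "lda"))
        rep(fit$prior, nrow(X))
      else predict(fit, X)$posterior[, "1"]
    })
  p <- as.numeric(p)
  p[!is.finite(p)] <- 0.5
  pmin(pmax(p, 0), 1)
}
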