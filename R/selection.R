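# Feature ranking: minimum-redundancy-maximum-relevance (MRMR, difference
# scheme) plus six univariate criteria (Fisher score, chi-square, Gini gain,
# mutual information, Spearman and Pearson correlation). Mutual information
# and the discretization-based criteria operate on 8-bin equal-frequency
# discretized features; ties are broken lexicographically by feature name so
# every ranking is deterministic.

# Equal-frequency discretization of each column into at most `bins` levels.
discretizeColumns <- function(X, bins = 8L) {
  apply(X, 2, function(x) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                          names = FALSE, type = 7))
    if (length(br) < 2L) return(rep(1L, length(x)))
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  })
}

# Plug-in mutual information (bits) between two integer codes.
miDiscrete <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  idx <- pj > 0
  sum(pj[idx] * log2(pj[idx] / outer(pa, pb)[idx]))
}

orderByScore <- function(score, featNames) {
  ord <- order(-score, featNames, method = "radix")
  ord
}

rankedList <- function(featNames, score, algorithm, K) {
  ord <- orderByScore(score, featNames)[seq_len(K)]
  out <- data.frame(rank = seq_len(K), feature = featNames[ord],
                    score = score[ord], stringsAsFactors = FALSE)
  attr(out, "algorithm") <- algorithm
  out
}

#' Minimum-redundancy-maximum-relevance feature ranking
#'
#' Greedy forward selection under the difference (MID) scheme: the first
#' pick maximizes mutual information with the label; each later pick
#' maximizes relevance minus the mean mutual information with the already
#' selected features. MI is estimated with a plug-in estimator on 8-bin
#' equal-frequency discretized features.
#'
#' @param X numeric matrix, samples x features, with column names.
#' @param y binary label vector (two classes).
#' @param K number of features to rank.
#' @return data.frame(rank, feature, score) with attribute `algorithm`.
#' @export
mrmrRank <- function(X, y, K) {
  featNames <- colnames(X)
  nf <- ncol(X)
  if (K > nf) stop("K exceeds the number of features")
  if (length(unique(y)) < 2L) stop("labels must contain two classes")
  Xd <- discretizeColumns(X)
  yd <- as.integer(factor(y))
  relevance <- vapply(seq_len(nf), function(j) miDiscrete(Xd[, j], yd), 0)
  selected <- integer(0)
  redundancySum <- numeric(nf)
  score <- numeric(K)
  remaining <- seq_len(nf)
  for (step in seq_len(K)) {
    if (step == 1L) {
      crit <- relevance[remaining]
    } else {
      last <- selected[length(selected)]
      for (j in remaining)
        redundancySum[j] <- redundancySum[j] + miDiscrete(Xd[, j], Xd[, last])
      crit <- relevance[remaining] - redundancySum[remaining] /
        length(selected)
    }
    pick <- remaining[orderByScore(crit, featNames[remaining])[1]]
    score[step] <- crit[match(pick, remaining)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  out <- data.frame(rank = seq_len(K), feature = featNames[selected],
                    score = score, stringsAsFactors = FALSE)
  attr(out, "algorithm") <- "MRMR"
  out
}

fisherScore <- function(x, y) {
  cl <- split(x, y)
  m <- vapply(cl, mean, 0)
  v <- vapply(cl, function(z) mean((z - mean(z))^2), 0)
  num <- (m[1] - m[2])^2
  den <- v[1] + v[2]
  unname(if (den == 0) {
    if (num == 0) 0 else Inf
  } else num / den)
}

chisqScore <- function(xd, y) {
  tab <- table(xd, y)
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  idx <- expd > 0
  sum((tab[idx] - expd[idx])^2 / expd[idx])
}

giniGain <- function(xd, y) {
  gini <- function(p) 1 - sum(p^2)
  py <- table(y) / length(y)
  base <- gini(as.vector(py))
  tab <- table(xd, y)
  w <- rowSums(tab) / length(y)
  child <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    gini(r / sum(r))
  }, 0)
  base - sum(w * child)
}

#' Univariate feature ranking
#'
#' Ranks features by one of six scores: Fisher score (`FSCR`), chi-square
#' statistic (`CHSQ`), Gini impurity gain (`GINI`), mutual information
#' (`MIM`), absolute Spearman (`SRCC`) or Pearson (`PRCC`) correlation with
#' the label. CHSQ, GINI and MIM operate on 8-bin equal-frequency
#' discretized features; a constant feature scores 0.
#'
#' @param X numeric matrix, samples x features, with column names.
#' @param y binary label vector.
#' @param method one of "FSCR", "CHSQ", "GINI", "MIM", "SRCC", "PRCC".
#' @param K number of features to rank.
#' @return data.frame(rank, feature, score) with attribute `algorithm`.
#' @export
univariateRank <- function(X, y, method = c("FSCR", "CHSQ", "GINI", "MIM",
                                            "SRCC", "PRCC"), K) {
  method <- match.arg(method)
  featNames <- colnames(X)
  if (K > ncol(X)) stop("K exceeds the number of features")
  if (length(unique(y)) < 2L) stop("labels must contain two classes")
  ynum <- as.numeric(factor(y))
  yd <- as.integer(factor(y))
  needsDisc <- method %in% c("CHSQ", "GINI", "MIM")
  Xd <- if (needsDisc) discretizeColumns(X) else NULL
  score <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    switch(method,
      FSCR = fisherScore(x, yd),
      CHSQ = chisqScore(Xd[, j], yd),
      GINI = giniGain(Xd[, j], yd),
      MIM = miDiscrete(Xd[, j], yd),
      SRCC = {
        r <- suppressWarnings(cor(x, ynum, method = "spearman"))
        if (is.na(r)) 0 else abs(r)
      },
      PRCC = {
        r <- suppressWarnings(cor(x, ynum))
        if (is.na(r)) 0 else abs(r)
      })
  }, 0)
  rankedList(featNames, score, method, K)
}

#' Rank features with any of the seven algorithms
#'
#' Dispatches to [mrmrRank()] for `"MRMR"` and to [univariateRank()]
#' otherwise.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param method selector tag.
#' @param K number of features.
#' @return ranking data.frame.
#' @export
rankFeatures <- function(X, y, method, K) {
  if (method == "MRMR") mrmrRank(X, y, K)
  else univariateRank(X, y, method, K)
}
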