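# Feature ranking: relevance, redundancy, degenerate scores, determinism.

makeXY <- function(n = 200L, seed = 13L) {
  set.seed(seed)
  y <- rep_len(c(0L, 1L), n)
  A <- 2 * y + rnorm(n, sd = 0.4)         # strongly informative
  B <- 0.8 * y + rnorm(n, sd = 1.0)       # weakly informative, independent
  X <- cbind(A = A, A_copy = A, B = B)
  list(X = X, y = y)
}

test_that("a feature equal to the label ranks first everywhere", {
  set.seed(5)
  y <- rep_len(c(0L, 1L), 80)
  X <- cbind(exact = as.numeric(y), noise1 = rnorm(80), noise2 = rnorm(80))
  expect_identical(mrmrRank(X, y, 3L)$feature[1], "exact")
  for (m in c("FSCR", "CHSQ", "GINI", "MIM", "SRCC", "PRCC"))
    expect_identical(univariateRank(X, y, m, 3L)$feature[1], "exact")
  # PRCC score of a +/-1 coded copy of the label is exactly 1
  X2 <- cbind(coded = ifelse(y == 1, 1, -1), noise = rnorm(80))
  r <- univariateRank(X2, y, "PRCC", 2L)
  expect_equal(r$score[1], 1)
})

test_that("MRMR demotes a duplicated feature below an independent one", {
  d <- makeXY()
  # oracle check of the construction: A most informative, the copy fully
  # redundant with it, B informative but independent
  Xd <- optomics:::discretizeColumns(d$X)
  miA <- oracleMi(Xd[, "A"], d$y)
  miB <- oracleMi(Xd[, "B"], d$y)
  expect_gt(miA, miB)
  expect_gt(oracleMi(Xd[, "A"], Xd[, "A_copy"]), miA)
  r <- mrmrRank(d$X, d$y, 3L)
  expect_identical(r$feature, c("A", "B", "A_copy"))
})

test_that("MRMR and MIM agree on the first pick", {
  for (seed in 1:20) {
    set.seed(100 + seed)
    n <- 60L
    y <- rep_len(c(0L, 1L), n)
    X <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(NULL, sprintf("f%d", 1:8)))
    X[, 1:3] <- X[, 1:3] + outer(y, runif(3, 0.3, 1.5))
    expect_identical(mrmrRank(X, y, 1L)$feature[1],
                     univariateRank(X, y, "MIM", 1L)$feature[1])
  }
})

test_that("Fisher score separates informative from independent features", {
  set.seed(77)
  n <- 1000L
  y <- rep_len(c(0L, 1L), n)
  X <- cbind(inf = y + rnorm(n, sd = 0.5), ind = rnorm(n))
  r <- univariateRank(X, y, "FSCR", 2L)
  expect_identical(r$feature[1], "inf")
  expect_lt(r$score[2] / r$score[1], 0.05)
  # identical class means and variances give a zero Fisher score
  xSame <- rep_len(c(-1, 1), n)
  ySame <- rep(c(0L, 1L), each = n / 2)
  expect_equal(optomics:::fisherScore(xSame, ySame), 0)
})

test_that("rankings are deterministic and sample-permutation invariant", {
  d <- makeXY(n = 120L, seed = 4L)
  perm <- sample(seq_along(d$y))
  for (m in c("MRMR", "FSCR", "MIM", "SRCC")) {
    r1 <- rankFeatures(d$X, d$y, m, 3L)
    r2 <- rankFeatures(d$X[perm, ], d$y[perm], m, 3L)
    expect_identical(r1$feature, r2$feature)
  }
  # K equal to the feature count returns a full permutation
  rAll <- mrmrRank(d$X, d$y, 3L)
  expect_setequal(rAll$feature, colnames(d$X))
  expect_error(mrmrRank(d$X, d$y, 4L), "exceeds")
  expect_error(mrmrRank(d$X, rep(1L, 120), 2L), "two classes")
  expect_error(univariateRank(d$X, d$y, "NOPE", 2L))
})
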