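# Probability maps: center probabilities, multi-scale averaging and the
# biharmonic spline interpolation contract.

test_that("patch probabilities attach to centers and respect the scale", {
  mt <- smallModelAndTable()
  pp <- patchProbabilities(mt$model, mt$table)
  info <- as.data.frame(SummarizedExperiment::colData(mt$table))
  expect_identical(pp$centerRow, info$centerRow)
  expect_true(all(pp$prob >= 0 & pp$prob <= 1))
  # scale mismatch is an error
  bad <- mt$model
  bad@scaleMm <- 0.9
  expect_error(patchProbabilities(bad, mt$table), "scale")
})

test_that("multi-scale averaging is the arithmetic mean with a fallback", {
  mk <- function(p) data.frame(centerRow = 1L, centerCol = 1L, prob = p)
  avg <- multiscaleAverage(list(mk(0.2), mk(0.4), mk(0.6)))
  expect_equal(avg$prob, 0.4)
  same <- multiscaleAverage(list(mk(0.31), mk(0.31), mk(0.31)))
  expect_equal(same$prob, 0.31)
  # center missing from one scale: mean over available, flagged
  two <- list(data.frame(centerRow = c(1L, 2L), centerCol = c(1L, 1L),
                         prob = c(1, 0.2)),
              data.frame(centerRow = 1L, centerCol = 1L, prob = 0))
  expect_warning(avg2 <- multiscaleAverage(two), "missing")
  expect_equal(avg2$prob[avg2$centerRow == 1L], 0.5)
  expect_true(avg2$partial[avg2$centerRow == 2L])
})

test_that("a single center yields a constant map", {
  mask <- matrix(TRUE, 9, 9)
  ctr <- data.frame(centerRow = 5L, centerCol = 5L, prob = 0.7)
  m <- biharmonicInterpolate(ctr, mask)
  expect_true(all(m == 0.7))
})

test_that("the interpolant reproduces nodal values", {
  set.seed(12)
  mask <- matrix(TRUE, 40, 40)
  pts <- unique(data.frame(centerRow = sample(40, 50, replace = TRUE),
                           centerCol = sample(40, 50, replace = TRUE)))
  pts$prob <- runif(nrow(pts))
  m <- biharmonicInterpolate(pts, mask, clip = FALSE)
  for (i in seq_len(nrow(pts)))
    expect_equal(m[pts$centerRow[i], pts$centerCol[i]], pts$prob[i],
                 tolerance = 1e-8)
})

test_that("symmetric corner values interpolate to 0.5 at the midpoint", {
  mask <- matrix(TRUE, 21, 21)
  ctr <- data.frame(centerRow = c(6L, 6L, 16L, 16L),
                    centerCol = c(6L, 16L, 6L, 16L),
                    prob = c(0, 1, 0, 1))
  m <- biharmonicInterpolate(ctr, mask)
  expect_equal(m[11, 11], 0.5, tolerance = 1e-8)
})

test_that("maps reflect with their inputs and clip only overshoot", {
  set.seed(3)
  mask <- matrix(TRUE, 25, 25)
  pts <- data.frame(centerRow = sample(2:24, 8),
                    centerCol = sample(2:24, 8), prob = runif(8))
  m <- biharmonicInterpolate(pts, mask, clip = FALSE)
  refl <- pts
  refl$centerCol <- 26L - pts$centerCol
  mr <- biharmonicInterpolate(refl, mask, clip = FALSE)
  expect_equal(mr[, 25:1], m, tolerance = 1e-8)
  clipped <- biharmonicInterpolate(pts, mask, clip = TRUE)
  expect_true(all(clipped >= 0 & clipped <= 1))
  expect_equal(clipped[m >= 0 & m <= 1], m[m >= 0 & m <= 1])
  # duplicate centers are averaged with a warning
  dup <- rbind(pts, transform(pts[1, ], prob = 1 - pts$prob[1]))
  expect_warning(biharmonicInterpolate(dup, mask), "duplicate")
})
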