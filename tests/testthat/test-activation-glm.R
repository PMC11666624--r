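rfFromShape <- function(times = seq(0, 8, by = 0.1)) {
  h <- responseShape(times)
  new("ResponseFunction", order = 10L, alpha = 0.6,
      coefficients = numeric(10), times = times, fitted = h, baseline = 0,
      peakAmplitude = 1, peakTime = 0.7, returnToBaselineTime = 3.7)
}

mapsFromMatrix <- function(Y, dmSpace = NULL) {
  # Y: frames x voxels
  if (is.null(dmSpace)) dmSpace <- c(ncol(Y), 1, 1)
  lapply(seq_len(nrow(Y)), function(t) {
    v <- array(Y[t, ], dmSpace)
    new("ConductivityMap", values = v, valid = array(is.finite(v), dmSpace),
        grid = VoxelGrid(dmSpace))
  })
}

test_that("design task column matches a dense convolution oracle", {
  rf <- rfFromShape()
  sched <- StimulusSchedule(onsets = 5, durations = 0.5)
  frameTimes <- seq(0.6, 40, by = 1.2)
  des <- buildDesign(sched, rf, frameTimes)
  # oracle: direct dense-grid convolution, sampled by interpolation
  g <- seq(0, 41.2, by = 0.1)
  box <- as.numeric(g >= 5 & g < 5.5)
  h <- rf@fitted
  dense <- sapply(seq_along(g), function(n) {
    k <- seq_len(min(n, length(h)))
    sum(h[k] * box[n - k + 1])
  })
  oracle <- approx(g, dense, xout = frameTimes)$y
  expect_equal(des@X[, "task"], oracle - mean(oracle), tolerance = 1e-8)
  # zero before the first onset (pre-centring)
  raw <- des@X[, "task"] + mean(oracle)
  expect_true(all(abs(raw[frameTimes < 5]) < 1e-12))

  # empty schedule: all-zero task column; the GLM later rejects it
  sched0 <- StimulusSchedule(numeric(0), numeric(0))
  des0 <- buildDesign(sched0, rf, frameTimes)
  expect_true(all(des0@X[, "task"] == 0))
  Y <- matrix(1, length(frameTimes), 2)
  expect_error(fitActivationGlm(mapsFromMatrix(Y), des0), "rank-deficient")
})

test_that("impulse response function reproduces the boxcar", {
  imp <- new("ResponseFunction", order = 1L, alpha = 0.5,
             coefficients = 1, times = seq(0, 2, by = 0.1),
             fitted = c(1, rep(0, 20)), baseline = 0, peakAmplitude = 1,
             peakTime = 0, returnToBaselineTime = 0.1)
  sched <- StimulusSchedule(onsets = 4, durations = 1.2)
  frameTimes <- seq(0.05, 12, by = 0.1)
  des <- buildDesign(sched, imp, frameTimes)
  raw <- des@X[, "task"] - min(des@X[, "task"])
  expect_equal(max(raw), 1, tolerance = 1e-9)
  expect_equal(raw[frameTimes > 4.2 & frameTimes < 5.0],
               rep(1, sum(frameTimes > 4.2 & frameTimes < 5.0)),
               tolerance = 1e-9)
  expect_equal(raw[frameTimes < 3.9],
               rep(0, sum(frameTimes < 3.9)), tolerance = 1e-9)

  expect_error(buildDesign(StimulusSchedule(onsets = 50, durations = 0.5),
                           imp, frameTimes), "outside the time range")
})

test_that("GLM recovers a noiseless broadcast regressor exactly", {
  rf <- rfFromShape()
  sched <- StimulusSchedule(onsets = c(5, 20), durations = 0.5)
  frameTimes <- seq(0.6, 36, by = 1.2)
  des <- buildDesign(sched, rf, frameTimes)
  Y <- matrix(rep(des@X[, "task"], 4), ncol = 4) + 0.5
  am <- fitActivationGlm(mapsFromMatrix(Y), des)
  expect_equal(as.vector(betaMap(am)), rep(1, 4), tolerance = 1e-9)
  expect_equal(dof(am), length(frameTimes) - 2)
  # residuals orthogonal to the design
  expect_true(all(is.finite(tMap(am))))
})

test_that("single-voxel t equals the closed-form beta / SE", {
  set.seed(50)
  rf <- rfFromShape()
  sched <- StimulusSchedule(onsets = 4, durations = 0.5)
  frameTimes <- seq(0.6, 14, by = 1.2)
  des <- buildDesign(sched, rf, frameTimes)
  X <- des@X
  y <- 0.4 + 0.3 * X[, "task"] + rnorm(nrow(X), 0, 0.05)
  am <- fitActivationGlm(mapsFromMatrix(matrix(y, ncol = 1)), des)
  # independent matrix-algebra oracle
  bhat <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% bhat
  s2 <- sum(res^2) / (nrow(X) - 2)
  se <- sqrt(s2 * solve(crossprod(X))[1, 1])
  expect_equal(betaMap(am)[1, 1, 1], bhat[1], tolerance = 1e-10)
  expect_equal(tMap(am)[1, 1, 1], bhat[1] / se, tolerance = 1e-10)
  # residual orthogonality (normal equations)
  expect_lt(max(abs(crossprod(X, res))), 1e-9)
})

test_that("t map is invariant to affine rescaling of the series", {
  set.seed(51)
  rf <- rfFromShape()
  sched <- StimulusSchedule(onsets = 4, durations = 0.5)
  frameTimes <- seq(0.6, 20, by = 1.2)
  des <- buildDesign(sched, rf, frameTimes)
  Y <- matrix(rnorm(length(frameTimes) * 6, 1, 0.1), ncol = 6)
  t1 <- tMap(fitActivationGlm(mapsFromMatrix(Y), des))
  t2 <- tMap(fitActivationGlm(mapsFromMatrix(3.2 * Y + 0.7), des))
  expect_equal(t1, t2, tolerance = 1e-8)
})

test_that("thresholding applies the display rule and the FDR option", {
  d <- c(4, 4, 2)
  tm <- array(seq(-3, 4, length.out = prod(d)), d)
  am <- new("ActivationMaps", beta = tm, tmap = tm, dof = 100,
            threshold = 2.2, valid = array(TRUE, d), grid = VoxelGrid(d))
  mask <- thresholdMap(am)
  expect_identical(mask, tm > 2.2)
  expect_false(any(thresholdMap(am, threshold = Inf)))
  expect_true(sum(thresholdMap(am, fdr = TRUE)) <= sum(mask))
})

test_that("null series t-statistics match the analytic t tail", {
  # pure Gaussian noise against a real design: empirical fraction above
  # 2.2 should match pt(2.2, dof) closely when pooled over seeds
  rf <- rfFromShape()
  sched <- StimulusSchedule(onsets = c(5, 20, 35), durations = 0.5)
  frameTimes <- seq(0.6, 48, by = 1.2)
  des <- buildDesign(sched, rf, frameTimes)
  Tn <- length(frameTimes)
  hits <- 0; total <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    Y <- matrix(rnorm(Tn * 500), nrow = Tn)
    am <- fitActivationGlm(mapsFromMatrix(Y, c(50, 10, 1)), des)
    hits <- hits + sum(tMap(am) > 2.2)
    total <- total + length(tMap(am))
  }
  expected <- pt(2.2, df = Tn - 2, lower.tail = FALSE)
  expect_lt(abs(hits / total - expected), 0.01)
})

test_that("voxels with too few valid frames are excluded, others fitted", {
  set.seed(52)
  rf <- rfFromShape()
  sched <- StimulusSchedule(onsets = 4, durations = 0.5)
  frameTimes <- seq(0.6, 30, by = 1.2)
  des <- buildDesign(sched, rf, frameTimes)
  Tn <- length(frameTimes)
  Y <- matrix(rnorm(Tn * 3, 1, 0.1), ncol = 3)
  Y[1:2, 2] <- NaN              # 2 of 25 frames missing: still >= 90%
  Y[1:6, 3] <- NaN              # 24% missing: excluded
  am <- fitActivationGlm(mapsFromMatrix(Y), des)
  expect_true(is.finite(tMap(am)[1, 1, 1]))
  expect_true(is.finite(tMap(am)[2, 1, 1]))
  expect_true(is.nan(tMap(am)[3, 1, 1]))
  expect_false(validMask(am)[3, 1, 1])
})
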