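makeMaps <- function(arr4d, grid = NULL) {
  d <- dim(arr4d)
  if (is.null(grid)) grid <- VoxelGrid(d[1:3])
  lapply(seq_len(d[4]), function(t) {
    v <- arr4d[, , , t, drop = TRUE]
    dim(v) <- d[1:3]
    new("ConductivityMap", values = v, valid = array(is.finite(v), d[1:3]),
        grid = grid)
  })
}

test_that("voxel selection keeps risers and drops fallers", {
  # 2-voxel toy embedded in a 2x1x1 grid over 10 frames, onset at 5 s
  arr <- array(0.5, c(2, 1, 1, 10))
  arr[1, 1, 1, 6:10] <- 0.6   # voxel A rises at first ON
  arr[2, 1, 1, 6:10] <- 0.4   # voxel B falls
  maps <- makeMaps(arr)
  sched <- StimulusSchedule(onsets = 5, durations = 0.5)
  meta <- AcquisitionMeta(dynamicDuration = 1)
  vox <- selectResponseVoxels(maps, sched, array(TRUE, c(2, 1, 1)), meta,
                              baselineFrac = 1)
  expect_equal(unname(vox[, 1]), 1L)
  expect_equal(nrow(vox), 1L)
  expect_true(all(attr(vox, "selectionFrames") %in% 1:6))

  # flat series: strict inequality never holds
  flat <- makeMaps(array(0.5, c(2, 1, 1, 10)))
  expect_equal(nrow(selectResponseVoxels(flat, sched,
                                         array(TRUE, c(2, 1, 1)), meta)), 0L)

  expect_error(selectResponseVoxels(maps, StimulusSchedule(numeric(0),
                                                           numeric(0)),
                                    array(TRUE, c(2, 1, 1)), meta), "empty")
  expect_error(selectResponseVoxels(maps, StimulusSchedule(0.2, 0.5),
                                    array(TRUE, c(2, 1, 1)), meta),
               "pre-onset")
})

test_that("selection recovers truly activated voxels on the phantom", {
  hits <- sapply(1:3, function(s) {
    ph <- makeDynamicPhantom(smallDynamicSpec(noiseStd = 3e-4, seed = s))
    maps <- reconSeries(ph$series, ph$magnitude, ph$labels,
                        bypassUnwrap = TRUE)
    meta <- acquisitionMeta(ph$series)
    roi <- ph$truth@activationMask
    vox <- selectResponseVoxels(maps, ph$schedule, roi, meta)
    valid1 <- validMask(maps[[1]]) & roi
    sel <- array(FALSE, dim(roi)); sel[vox] <- TRUE
    sum(sel & valid1) / sum(valid1)
  })
  expect_true(all(hits >= 0.9))
})

test_that("half-scan timing convention places frames at mid-acquisition", {
  arr <- array(1, c(1, 1, 1, 13))
  maps <- makeMaps(arr)
  sched <- StimulusSchedule(onsets = 0, durations = 0.5)
  meta <- AcquisitionMeta(dynamicDuration = 1.2)
  tc <- poolJittered(maps, sched, matrix(c(1, 1, 1), 1), meta,
                     window = c(0, 16))
  # first frame lands at t = 0.6 s (half of the 1.2 s dynamic scan)
  expect_equal(min(tc@times[tc@counts > 0]), 0.6)
})

test_that("16 jitters tile the 100 ms pooled grid", {
  sched <- defaultJitterSchedule()
  nT <- 212L
  arr <- array(1, c(1, 1, 1, nT))
  maps <- makeMaps(arr)
  meta <- AcquisitionMeta(dynamicDuration = 1.2)
  tc <- poolJittered(maps, sched, matrix(c(1, 1, 1), 1), meta,
                     window = c(-2, 13.4))
  expect_equal(diff(tc@times), rep(0.1, length(tc@times) - 1),
               tolerance = 1e-9)
  # every bin of the covered window is populated (the fixed jitter order
  # is designed to cover all residues of the frame duration)
  expect_true(all(tc@counts[tc@times > -1.7 & tc@times < 12.9] > 0))
})

test_that("pooling matches a brute-force (cycle, frame) enumeration", {
  set.seed(31)
  nT <- 30L
  arr <- array(rnorm(nT, 1, 0.1), c(1, 1, 1, nT))
  maps <- makeMaps(arr)
  sched <- StimulusSchedule(onsets = c(5, 15), durations = 0.5,
                            jitters = c(0, 0.1))
  meta <- AcquisitionMeta(dynamicDuration = 1.2)
  win <- c(-2, 8)
  tc <- poolJittered(maps, sched, matrix(c(1, 1, 1), 1), meta, window = win)

  # oracle: enumerate all (cycle, frame) pairs and bin by nearest centre
  tmid <- (seq_len(nT) - 1) * 1.2 + 0.6
  ons <- onsets(sched) + jitterOffsets(sched)
  samp <- data.frame(t = as.vector(outer(tmid, ons, "-")),
                     v = rep(arr[1, 1, 1, ], length(ons)))
  samp <- samp[samp$t >= win[1] & samp$t <= win[2], ]
  bin <- ceiling(samp$t / 0.1 - 0.5)
  for (b in unique(bin)) {
    i <- which(abs(tc@times - b * 0.1) < 1e-9)
    expect_equal(tc@counts[i], sum(bin == b))
    expect_equal(tc@values[i], mean(samp$v[bin == b]))
  }
  # sample conservation over the window
  expect_equal(sum(tc@counts), nrow(samp))
})

test_that("discrete Laguerre basis is orthonormal with the right limits", {
  B <- laguerreBasis(10, 0.5, seq(0, 19.9, by = 0.1))
  expect_equal(crossprod(B), diag(10), tolerance = 1e-10)
  # order 1: geometric decay, unit norm
  b1 <- laguerreBasis(1, 0.3, 1:300)
  expect_equal(sum(b1^2), 1, tolerance = 1e-10)
  expect_equal(b1[2] / b1[1], sqrt(0.3), tolerance = 1e-12)
  # alpha -> 0: first function approaches a unit impulse at index 0
  b0 <- laguerreBasis(1, 1e-9, 1:50)
  expect_equal(b0[1], 1, tolerance = 1e-8)
  expect_lt(max(abs(b0[-1])), 1e-4)
  expect_error(laguerreBasis(10, 1, 1:10), "alpha")
  expect_error(laguerreBasis(10, 0, 1:10), "alpha")
})

test_that("response fit recovers in-span curves and peak metrics", {
  times <- seq(0, 12, by = 0.1)
  B <- laguerreBasis(10, 0.6, times)
  # all-zero timecourse
  tc0 <- new("PooledTimecourse", times = times,
             values = numeric(length(times)),
             counts = rep(1L, length(times)))
  rf0 <- fitResponse(tc0, alpha = 0.6)
  expect_equal(peakAmplitude(rf0), 0, tolerance = 1e-12)
  expect_equal(coef(rf0), rep(0, 10), tolerance = 1e-12)

  # 2x the third basis function: coefficients recovered, residual
  # orthogonal to the basis (normal-equation identity)
  y <- 2 * B[, 3]
  tc <- new("PooledTimecourse", times = times, values = y,
            counts = rep(1L, length(times)))
  rf <- fitResponse(tc, alpha = 0.6)
  expect_equal(coef(rf), c(0, 0, 2, rep(0, 7)), tolerance = 1e-8)
  resid <- y - (fitted(rf) - rf@baseline)
  expect_lt(max(abs(crossprod(B, resid))), 1e-8)

  # a gamma-like curve with baseline: peak metrics
  h <- 0.1 * responseShape(times) + 0.4
  pre <- seq(-1, -0.1, by = 0.1)
  tcb <- new("PooledTimecourse", times = c(pre, times),
             values = c(rep(0.4, length(pre)), h),
             counts = rep(2L, length(pre) + length(times)))
  rfb <- fitResponse(tcb)
  expect_equal(rfb@baseline, 0.4, tolerance = 1e-12)
  expect_equal(peakAmplitude(rfb), 0.1, tolerance = 0.005)
  expect_equal(peakTime(rfb), 0.7, tolerance = 0.1)
  expect_equal(returnToBaselineTime(rfb), 3.7, tolerance = 0.3)

  expect_error(fitResponse(new("PooledTimecourse", times = times[1:5],
                               values = rep(1, 5), counts = rep(1L, 5))),
               "rank")
})

test_that("simple linear regression matches the closed form", {
  # exactly collinear points (lm warns about the perfect fit; expected)
  fit <- suppressWarnings(
    stimulusResponseRegression(c(1, 2, 3), c(0.1, 0.2, 0.3)))
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
  expect_equal(fit@slope, 10, tolerance = 1e-12)

  # hand-computed normal equations for (0.1,1), (0.2,2), (0.3,2.5)
  x <- c(0.1, 0.2, 0.3); y <- c(1, 2, 2.5)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fit <- stimulusResponseRegression(y, x)
  expect_equal(fit@slope, slope, tolerance = 1e-12)
  expect_equal(fit@intercept, mean(y) - slope * mean(x), tolerance = 1e-12)

  # the duration design of the stimulus-response experiment is accepted
  fit <- stimulusResponseRegression(c(0.02, 0.05, 0.06, 0.08, 0.1),
                                    c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_gt(fit@rSquared, 0.9)
  expect_error(stimulusResponseRegression(c(1, 2), c(1, 2)), "3 points")
  expect_error(stimulusResponseRegression(c(1, 2, 3), c(2, 2, 2)),
               "constant")
})

test_that("one-way ICC matches the ANOVA decomposition", {
  # identical repeats per subject: ICC = 1
  m <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(iccOneway(m), 1)

  # 3 subjects x 2 repeats toy table vs hand ANOVA
  m <- rbind(c(1.0, 1.2), c(2.0, 1.8), c(3.1, 2.9))
  grand <- mean(m)
  ssb <- 2 * sum((rowMeans(m) - grand)^2)
  ssw <- sum((m - rowMeans(m))^2)
  msb <- ssb / 2; msw <- ssw / 3
  expect_equal(iccOneway(m), (msb - msw) / (msb + msw), tolerance = 1e-12)

  # pure noise: ICC ~ 0 over 1000 simulated tables
  set.seed(40)
  iccs <- replicate(1000, iccOneway(matrix(rnorm(12), 6, 2)))
  expect_lt(abs(mean(iccs)), 0.05)
  expect_error(iccOneway(matrix(1:2, 1)), "2 subjects")
})
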