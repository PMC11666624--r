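test_that("kernel neighbourhood applies box, tissue and amplitude rules", {
  d <- c(13, 13, 10)
  vols <- uniformVolumes(array(0, d), tissue = 1L)
  target <- c(7L, 7L, 5L)
  nb <- kernelNeighborhood(target, vols$phase, vols$magnitude, vols$labels)
  # uniform single-tissue volume: the full 9 x 9 x 6-extent box minus target
  expect_equal(nrow(nb), 9 * 9 * 7 - 1)

  # tissue restriction: a WM slab next to the GM target is never recruited
  lab <- array(1L, d); lab[9:13, , ] <- 2L
  vols$labels <- TissueLabelMap(lab, voxelGrid(vols$labels))
  nb <- kernelNeighborhood(target, vols$phase, vols$magnitude, vols$labels)
  expect_true(all(nb[, 1] <= 8))

  # amplitude rule vs a brute-force filter oracle
  set.seed(20)
  mag <- array(runif(prod(d), 0.8, 1.3), c(13, 13, 10))
  vols$magnitude <- MagnitudeVolume(mag, voxelGrid(vols$labels))
  spec <- KernelSpec()
  nb <- kernelNeighborhood(target, vols$phase, vols$magnitude, vols$labels,
                           spec)
  oracle <- expand.grid(i = 3:11, j = 3:11, k = 2:8)
  oracle <- oracle[!(oracle$i == 7 & oracle$j == 7 & oracle$k == 5), ]
  mt <- mag[7, 7, 5]
  keep <- lab[as.matrix(oracle)] == 1L &
    abs(mag[as.matrix(oracle)] - mt) <= spec@amplitudeTol * mt
  expect_setequal(apply(nb, 1, paste, collapse = ","),
                  apply(as.matrix(oracle[keep, ]), 1, paste, collapse = ","))
  expect_error(kernelNeighborhood(c(1L, 1L, 1L), vols$phase,
                                  vols$magnitude,
                                  TissueLabelMap(array(0L, d))),
               "background")
})

test_that("parabolic 1D second derivative is exact on polynomials", {
  x <- -4:4
  # parabola: exact second derivative, accepted with correlation 1
  r <- parabolicSecondDerivative(x^2, center = 5, spacing = 1)
  expect_equal(r$secondDerivative, 2, tolerance = 1e-10)
  expect_true(r$accepted)
  expect_equal(r$fitCorr, 1, tolerance = 1e-9)

  # straight line: zero curvature, accepted (constant fit edge case inside)
  r <- parabolicSecondDerivative(3 * x + 1, center = 5, spacing = 1)
  expect_equal(r$secondDerivative, 0, tolerance = 1e-10)
  expect_true(r$accepted)

  # cubic: equals the mean of the two one-sided dense least-squares fits
  y <- as.numeric(x^3)
  left <- quadFitSecondDeriv(c(-4:-1, 0), y[c(1:4, 5)])
  right <- quadFitSecondDeriv(c(0, 1:4), y[c(5, 6:9)])
  r <- parabolicSecondDerivative(y, center = 5, spacing = 1)
  expect_equal(r$secondDerivative, mean(c(left, right)), tolerance = 1e-8)

  # physical spacing scales the result by 1/h^2
  r2 <- parabolicSecondDerivative(x^2, center = 5, spacing = 0.003)
  expect_equal(r2$secondDerivative, 2 / 0.003^2, tolerance = 1e-6)

  # one usable side only still yields an estimate; none yields invalid
  r <- parabolicSecondDerivative(c(NA, NA, NA, NA, 0, 1, 4, 9, 16),
                                 center = 5, spacing = 1)
  expect_true(r$accepted)
  expect_equal(r$secondDerivative, 2, tolerance = 1e-8)
  r <- parabolicSecondDerivative(c(NA, NA, NA, 1, 0, 1, NA, NA, NA),
                                 center = 5, spacing = 1)
  expect_false(r$accepted)
  expect_true(is.na(r$secondDerivative))
})

test_that("quadratic phase yields the exact analytic Laplacian", {
  d <- c(16, 16, 12)
  cc <- 0.7
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  r2vox <- outer(outer((idx[[1]] - 8)^2, (idx[[2]] - 8)^2, "+"),
                 (idx[[3]] - 6)^2, "+")
  vols <- uniformVolumes(cc * r2vox, spacingMm = c(1, 1, 1))
  lap <- phaseLaplacian(vols$phase, vols$magnitude, vols$labels)
  interior <- array(FALSE, d); interior[5:12, 5:12, 4:9] <- TRUE
  expect_equal(values(lap)[interior],
               rep(6 * cc * 1e6, sum(interior)), tolerance = 1e-9)
  expect_true(all(validMask(lap)[interior]))

  # constant phase: zero Laplacian everywhere valid
  vols0 <- uniformVolumes(array(4, d))
  lap0 <- phaseLaplacian(vols0$phase, vols0$magnitude, vols0$labels)
  expect_equal(max(abs(values(lap0)[validMask(lap0)])), 0, tolerance = 1e-12)

  expect_error(
    phaseLaplacian(vols$phase, vols$magnitude,
                   TissueLabelMap(array(1L, c(4, 4, 4)))),
    "share one grid")
})

test_that("phase linearity: scaling phase scales every valid sigma", {
  ph <- makeStaticPhantom(defaultStaticPhantomSpec(n = 24L))
  lap1 <- phaseLaplacian(ph$phase, ph$magnitude, ph$labels)
  ph2 <- PhaseVolume(3 * values(ph$phase), voxelGrid(ph$phase))
  lap2 <- phaseLaplacian(ph2, ph$magnitude, ph$labels)
  s1 <- phaseToConductivity(lap1, sigmaWindow = c(-10, 10))
  s2 <- phaseToConductivity(lap2, sigmaWindow = c(-10, 10))
  expect_identical(validMask(s1), validMask(s2))
  expect_equal(values(s2)[validMask(s2)], 3 * values(s1)[validMask(s1)],
               tolerance = 1e-9)
})

test_that("conductivity conversion uses the 3 T transceive constant", {
  d <- c(3, 3, 3)
  # 2 * mu0 * omega for omega = 2*pi * 127.76e6 rad/s: a Laplacian of this
  # size must convert to exactly 1 S/m under the 3 T default
  k3T <- 2 * (4e-7 * pi) * (2 * pi * 127.76e6)
  lap <- new("LaplacianMap", values = array(k3T, d),
             valid = array(TRUE, d),
             neighborCount = array(100L, d), grid = VoxelGrid(d))
  cm <- phaseToConductivity(lap, AcquisitionMeta())
  expect_equal(values(cm)[1], 1, tolerance = 1e-12)
  lap0 <- new("LaplacianMap", values = array(0, d), valid = array(TRUE, d),
              neighborCount = array(100L, d), grid = VoxelGrid(d))
  expect_equal(values(phaseToConductivity(lap0))[1], 0)
  expect_error(AcquisitionMeta(larmorHz = 0), "larmorHz")
})

test_that("forward model inverts exactly: sigma_true = 0.6 S/m phantom", {
  grid <- VoxelGrid(c(20, 20, 16), c(2, 2, 2))
  spec <- PhantomSpec(grid, list(list(shape = "sphere", center = c(10, 10, 8),
                                      radius = 8, tissue = "GM",
                                      sigma = 0.6)))
  ph <- makeStaticPhantom(spec)
  cm <- phaseToConductivity(
    phaseLaplacian(ph$phase, ph$magnitude, ph$labels))
  inner <- values(ph$labels) == 1L
  # erode: keep voxels whose full kernel row support is in-tissue
  idx <- which(inner, arr.ind = TRUE)
  ctr <- c(10, 10, 8)
  core <- idx[sqrt(rowSums((idx - rep(ctr, each = nrow(idx)))^2)) <= 3, ]
  expect_equal(values(cm)[core], rep(0.6, nrow(core)), tolerance = 1e-6)
})

test_that("two-compartment phantom: interiors exact, boundaries never silently wrong", {
  ph <- makeStaticPhantom(defaultStaticPhantomSpec(n = 48L))
  cm <- phaseToConductivity(
    phaseLaplacian(ph$phase, ph$magnitude, ph$labels))
  truth <- ph$truth@sigmaMap
  lab <- values(ph$labels)
  for (code in c(1L, 2L)) {
    m <- lab == code
    idx <- which(m, arr.ind = TRUE)
    # interior = all voxels of the 9x9x7 kernel box share the tissue
    keep <- vapply(seq_len(nrow(idx)), function(r) {
      i <- idx[r, ]
      if (any(i <= 4) || any(i > dim(lab) - c(4, 4, 3))) return(FALSE)
      all(lab[(i[1] - 4):(i[1] + 4), (i[2] - 4):(i[2] + 4),
              (i[3] - 3):(i[3] + 3)] == code)
    }, logical(1))
    core <- idx[keep, , drop = FALSE]
    expect_gt(nrow(core), 0)
    expect_equal(values(cm)[core], truth[core],
                 tolerance = 1e-6)
  }
  # every valid in-tissue voxel is correct; misfit voxels are flagged
  ok <- validMask(cm) & lab > 0
  expect_lt(max(abs(values(cm)[ok] - truth[ok])), 1e-6)
})

test_that("parabolic Laplacian tracks central differences on smooth fields", {
  # band-limited sinusoidal field, wavelength 96 voxels
  d <- c(32, 32, 24)
  k <- 2 * pi / 96
  f <- outer(outer(sin(k * seq_len(d[1])), sin(k * seq_len(d[2])), "*"),
             sin(k * seq_len(d[3])), "*")
  vols <- uniformVolumes(5 * f, spacingMm = c(2, 2, 2))
  lap <- phaseLaplacian(vols$phase, vols$magnitude, vols$labels)
  fd <- centralDifferenceLaplacian(5 * f, c(2, 2, 2))
  sel <- array(FALSE, d); sel[6:27, 6:27, 5:20] <- TRUE
  sel <- sel & abs(fd) >= 0.5 * max(abs(fd), na.rm = TRUE)
  relErr <- abs(values(lap)[sel] - fd[sel]) / abs(fd[sel])
  expect_lt(max(relErr), 0.01)
})

test_that("reconstruction error grows with phase noise", {
  rmse <- sapply(c(0, 0.05, 0.1, 0.2), function(ns) {
    mean(sapply(1:3, function(s) {
      ph <- makeStaticPhantom(defaultStaticPhantomSpec(
        n = 20L, noiseStd = ns, seed = s))
      cm <- phaseToConductivity(
        phaseLaplacian(ph$phase, ph$magnitude, ph$labels),
        sigmaWindow = c(-50, 50))
      ok <- validMask(cm)
      sqrt(mean((values(cm)[ok] - ph$truth@sigmaMap[ok])^2))
    }))
  })
  expect_true(all(diff(rmse) >= 0))
})

test_that("framewise reconstruction is consistent across a static series", {
  spec <- smallDynamicSpec(amplitude = 0, noiseStd = 0, nCycles = 2L)
  ph <- makeDynamicPhantom(spec)
  maps <- reconSeries(ph$series, ph$magnitude, ph$labels,
                      bypassUnwrap = TRUE)
  expect_identical(validMask(maps[[1]]), validMask(maps[[5]]))
  expect_equal(values(maps[[1]]), values(maps[[5]]), tolerance = 1e-12)
  # dynamic truth: framewise ROI sigma equals injected truth (noiseless)
  ph2 <- makeDynamicPhantom(smallDynamicSpec(amplitude = 0.1,
                                             noiseStd = 0, nCycles = 2L))
  maps2 <- reconSeries(ph2$series, ph2$magnitude, ph2$labels,
                       bypassUnwrap = TRUE)
  roi <- ph2$truth@activationMask
  core <- array(FALSE, dim(roi))
  ctr <- c(13 + 4, 13, 10)  # ROI centre of the small phantom sphere
  core[ctr[1] + (-1:1), ctr[2] + (-1:1), ctr[3] + (-1:1)] <- TRUE
  meta <- acquisitionMeta(ph2$series)
  tmid <- frameMidTimes(ph2$series)
  onsets <- onsets(ph2$schedule) + jitterOffsets(ph2$schedule)
  for (k in c(1, 10, 14)) {
    h <- sum(responseShape(tmid[k] - onsets))
    expect_equal(mean(values(maps2[[k]])[core]), 0.64 + 0.1 * h,
                 tolerance = 1e-6)
  }
})

test_that("neighbour-count diagnostics mirror the kernel histogram", {
  ph <- makeStaticPhantom(defaultStaticPhantomSpec(n = 24L))
  lap <- phaseLaplacian(ph$phase, ph$magnitude, ph$labels)
  hg <- neighborCountHistogram(lap, ph$labels)
  expect_true(hg$fractionAtLeast > 0.8)
  expect_equal(sum(hg$histogram), sum(values(ph$labels) > 0))
})
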