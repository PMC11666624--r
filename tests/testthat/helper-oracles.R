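# Independent oracles and small generators shared by the test files.

# 7-point central-difference Laplacian in rad/m^2 (independent of the
# parabolic-fit path); NA on the one-voxel border.
centralDifferenceLaplacian <- function(values, spacingMm) {
  d <- dim(values)
  sp <- spacingMm / 1000
  out <- array(NA_real_, d)
  i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
  out[i, j, k] <-
    (values[i + 1, j, k] - 2 * values[i, j, k] + values[i - 1, j, k]) / sp[1]^2 +
    (values[i, j + 1, k] - 2 * values[i, j, k] + values[i, j - 1, k]) / sp[2]^2 +
    (values[i, j, k + 1] - 2 * values[i, j, k] + values[i, j, k - 1]) / sp[3]^2
  out
}

# 1D Itoh unwrapping: cumulative sum of wrapped differences.
itohUnwrap1d <- function(wrapped) {
  d <- diff(wrapped)
  d <- d - 2 * pi * round(d / (2 * pi))
  wrapped[1] + c(0, cumsum(d))
}

# dense least-squares quadratic fit oracle for one side (target + side
# voxels), returning the second derivative; positions in voxel units
quadFitSecondDeriv <- function(x, y) {
  fit <- stats::lm(y ~ x + I(x^2))
  2 * unname(stats::coef(fit)[3])
}

# single-tissue uniform-magnitude volume triple around a given phase array
uniformVolumes <- function(phaseArr, spacingMm = c(1, 1, 1), tissue = 1L) {
  grid <- VoxelGrid(dim(phaseArr), spacingMm)
  list(phase = PhaseVolume(phaseArr, grid),
       magnitude = MagnitudeVolume(array(1, dim(phaseArr)), grid),
       labels = TissueLabelMap(array(tissue, dim(phaseArr)), grid))
}

# small dynamic phantom for fast functional tests (same structure as the
# default, scaled down)
smallDynamicSpec <- function(amplitude = 0.1, noiseStd = 0, seed = 1L,
                             nCycles = 4L) {
  grid <- VoxelGrid(c(24L, 24L, 18L), rep(3.75, 3))
  ctr <- (grid@shape + 1) / 2
  roi <- list(shape = "sphere", center = c(ctr[1] + 4, ctr[2], ctr[3]),
              radius = 4, tissue = "GM", sigma = 0.64)
  comps <- list(
    list(shape = "ellipsoid", center = ctr, semiaxes = c(10, 10, 7.5),
         tissue = "WM", sigma = 0.42),
    roi)
  sched <- defaultJitterSchedule(nCycles = nCycles)
  PhantomSpec(grid, comps, noiseStd = noiseStd, wrap = FALSE,
              activation = list(roi = roi, amplitude = amplitude,
                                peakTime = 0.7, returnTime = 3.7,
                                onsetDelay = 0, schedule = sched),
              phaseCenter = ctr - c(15, 14, 11),
              meta = AcquisitionMeta(dynamicDuration = 1.2), seed = seed)
}
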