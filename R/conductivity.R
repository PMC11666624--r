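#' Kernel neighbourhood of a target voxel
#'
#' All voxels within the kernel box (symmetric reach floor(extent / 2) per
#' side) that share the target's tissue label and whose image amplitude is
#' within \code{amplitudeTol} (relative) of the target's. Voxels near tissue
#' boundaries therefore never recruit neighbours from a different tissue,
#' and amplitude outliers are excluded — the two rules that suppress
#' boundary artefacts in the Laplacian.
#'
#' @param target 1-based voxel index, integer length 3
#' @param phase a \linkS4class{PhaseVolume}
#' @param magnitude a \linkS4class{MagnitudeVolume}
#' @param labels a \linkS4class{TissueLabelMap}
#' @param spec a \linkS4class{KernelSpec}
#' @return integer matrix (n x 3) of neighbour indices (target excluded)
#' @export
kernelNeighborhood <- function(target, phase, magnitude, labels,
                               spec = KernelSpec()) {
  target <- as.integer(target)
  dm <- dim(labels@values)
  lab <- labels@values[target[1], target[2], target[3]]
  if (lab == 0L) stop("target voxel is background")
  reach <- spec@maxExtent %/% 2L
  rng <- lapply(1:3, function(a)
    max(1L, target[a] - reach[a]):min(dm[a], target[a] + reach[a]))
  box <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  keep <- !(box[, 1] == target[1] & box[, 2] == target[2] &
            box[, 3] == target[3])
  box <- box[keep, , drop = FALSE]
  mt <- magnitude@values[target[1], target[2], target[3]]
  lv <- labels@values[box]
  mv <- magnitude@values[box]
  pv <- phase@values[box]
  ok <- lv == lab & abs(mv - mt) <= spec@amplitudeTol * mt & is.finite(pv)
  box[ok, , drop = FALSE]
}

#' One-axis second derivative by average parabolic fitting
#'
#' Least-squares parabolas are fitted separately to \{target + left-side
#' voxels\} and \{target + right-side voxels\}; the returned second
#' derivative is the mean of the available one-sided values. A side needs at
#' least 2 usable voxels besides the target or it is dropped; if both sides
#' drop, the estimate is invalid (flagged, not an error). A side is accepted
#' only when the Pearson correlation between fitted and measured phase
#' exceeds \code{spec@minCorr}; a zero-variance (constant) sample counts as
#' correlation 1, since a constant is fitted exactly.
#'
#' @param samples ordered phase values along one axis through the target
#'   (radians); NA marks excluded voxels
#' @param center 1-based position of the target within \code{samples};
#'   defaults to the middle
#' @param spacing voxel spacing along the axis, metres
#' @param spec a \linkS4class{KernelSpec}
#' @param reach voxels per side entering the fit; defaults to
#'   floor(max(extent) / 2)
#' @return list(secondDerivative (rad/m^2, NA if invalid), accepted,
#'   fitCorr (min over used sides))
#' @export
parabolicSecondDerivative <- function(samples, center = (length(samples) + 1) %/% 2,
                                      spacing = 1, spec = KernelSpec(),
                                      reach = max(spec@maxExtent) %/% 2L) {
  r <- cpp_parfit_row(as.numeric(samples), as.integer(center) - 1L,
                      as.numeric(spacing), spec@minCorr, as.integer(reach))
  list(secondDerivative = r$second_derivative, accepted = r$accepted,
       fitCorr = r$fit_corr)
}

#' Tissue-restricted parabolic-fit Laplacian
#'
#' Per voxel, a 1D second derivative is estimated along each axis by average
#' parabolic fitting over the kernel rows (see
#' \code{\link{parabolicSecondDerivative}}), restricted to same-tissue,
#' similar-amplitude voxels, and the Laplacian is the sum over the three
#' axes (each converted with its physical spacing). A voxel is valid iff all
#' three axes were accepted and the 3D kernel neighbourhood holds at least
#' \code{spec@minNeighbors} surrounding voxels; the neighbour count is
#' recorded for diagnostics.
#'
#' @param phase an unwrapped (and typically denoised) \linkS4class{PhaseVolume}
#' @param magnitude a \linkS4class{MagnitudeVolume} on the same grid
#' @param labels a \linkS4class{TissueLabelMap} on the same grid
#' @param spec a \linkS4class{KernelSpec}
#' @return a \linkS4class{LaplacianMap} (values in rad/m^2)
#' @export
phaseLaplacian <- function(phase, magnitude, labels, spec = KernelSpec()) {
  stopifnot(is(phase, "PhaseVolume"), is(magnitude, "MagnitudeVolume"),
            is(labels, "TissueLabelMap"))
  if (isWrapped(phase)) stop("phase must be unwrapped")
  dm <- dim(phase@values)
  if (!all(dm == dim(magnitude@values)) || !all(dm == dim(labels@values)))
    stop("phase, magnitude and labels must share one grid")
  if (max(abs(phase@grid@spacing - labels@grid@spacing)) > 1e-9)
    stop("phase, magnitude and labels must share one grid")
  res <- cpp_laplacian(as.numeric(phase@values),
                       as.numeric(magnitude@values),
                       as.integer(labels@values), as.integer(dm),
                       as.numeric(phase@grid@spacing) / 1000,  # mm -> m
                       as.integer(spec@maxExtent %/% 2L),
                       spec@amplitudeTol, spec@minCorr,
                       spec@minNeighbors)
  new("LaplacianMap", values = array(res$values, dm),
      valid = array(res$valid, dm),
      neighborCount = array(res$neighbor_count, dm), grid = phase@grid)
}

#' Convert a phase Laplacian to conductivity
#'
#' sigma = Laplacian(phi) / (2 * mu0 * omega) with omega = 2 * pi *
#' larmorHz. The factor 2 embodies the transceive-phase assumption: the
#' transmit phase is half the measured transceive phase, so the input must
#' be the full transceive phase. Valid conductivities outside the
#' plausibility window are invalidated (NaN).
#'
#' @param lap a \linkS4class{LaplacianMap}
#' @param meta an \linkS4class{AcquisitionMeta} (larmorHz > 0)
#' @param sigmaWindow plausibility window in S/m
#' @return a \linkS4class{ConductivityMap}
#' @export
phaseToConductivity <- function(lap, meta = AcquisitionMeta(),
                                sigmaWindow = KernelSpec()@sigmaWindow) {
  stopifnot(is(lap, "LaplacianMap"))
  if (meta@larmorHz <= 0) stop("larmorHz must be > 0")
  omega <- 2 * pi * meta@larmorHz
  vals <- lap@values / (2 * meta@mu0 * omega)
  valid <- lap@valid & is.finite(vals) &
    vals >= sigmaWindow[1] & vals <= sigmaWindow[2]
  vals[!valid] <- NaN
  new("ConductivityMap", values = vals, valid = valid, grid = lap@grid)
}

#' Framewise conductivity reconstruction of a dynamic series
#'
#' Applies the tissue-restricted Laplacian and the phase-to-conductivity
#' conversion to every frame with identical validity logic.
#'
#' @param series an unwrapped \linkS4class{DynamicPhaseSeries} (or use
#'   \code{bypassUnwrap} when the stored frames are already continuous)
#' @param magnitude a \linkS4class{MagnitudeVolume}
#' @param labels a \linkS4class{TissueLabelMap}
#' @param spec a \linkS4class{KernelSpec}
#' @param bypassUnwrap treat frames as already unwrapped
#' @return list of \linkS4class{ConductivityMap}, one per frame
#' @export
reconSeries <- function(series, magnitude, labels, spec = KernelSpec(),
                        bypassUnwrap = FALSE) {
  stopifnot(is(series, "DynamicPhaseSeries"))
  if (isWrapped(series) && !bypassUnwrap)
    stop("series is wrapped: unwrap frames first or set bypassUnwrap = TRUE")
  meta <- series@meta
  lapply(seq_len(nFrames(series)), function(t) {
    fr <- PhaseVolume(series@values[, , , t, drop = TRUE],
                      grid = series@grid, wrapped = FALSE)
    phaseToConductivity(phaseLaplacian(fr, magnitude, labels, spec),
                        meta = meta, sigmaWindow = spec@sigmaWindow)
  })
}

#' Neighbour-count diagnostics for a Laplacian map
#'
#' Histogram of the number of surrounding voxels used per kernel, plus the
#' fraction of in-tissue voxels with at least \code{atLeast} neighbours.
#'
#' @param lap a \linkS4class{LaplacianMap}
#' @param labels optional \linkS4class{TissueLabelMap} restricting the
#'   tally to in-tissue voxels
#' @param atLeast threshold for the reported fraction (default 6)
#' @return list(histogram = table, fractionAtLeast = numeric)
#' @export
neighborCountHistogram <- function(lap, labels = NULL, atLeast = 6L) {
  stopifnot(is(lap, "LaplacianMap"))
  counts <- lap@neighborCount
  sel <- if (is.null(labels)) counts > 0 | lap@valid else labels@values > 0
  counts <- counts[sel]
  list(histogram = table(counts),
       fractionAtLeast = mean(counts >= atLeast))
}
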