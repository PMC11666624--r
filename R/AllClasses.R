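#' @import methods
NULL

#' Magnetic permeability of free space (H/m)
#'
#' SI constant used in the phase-to-conductivity conversion
#' sigma = Laplacian(phi) / (2 * mu0 * omega).
#' @export
MU0 <- 4e-7 * pi

#' Default proton Larmor frequency at 3 T (Hz)
#'
#' The 3 T default corresponds to omega = 2 * pi * 127.76e6 rad/s.
#' @export
DEFAULT_LARMOR_HZ <- 127.76e6

TISSUE_CODES <- c(background = 0L, GM = 1L, WM = 2L, CSF = 3L)

## ---------------------------------------------------------------------------
## Geometry and volumes
## ---------------------------------------------------------------------------

#' VoxelGrid: voxel geometry of a volume
#'
#' Shape (voxels per axis), spacing in millimetres, and a 4x4 voxel-to-world
#' affine. Voxel indices are 0-based in world-coordinate computations, after
#' NIfTI convention; kernels operate in voxel space and physical spacing is
#' applied only when differentiating.
#'
#' @slot shape integer length-3, voxels per axis, each >= 1
#' @slot spacing numeric length-3, mm per axis, each > 0
#' @slot affine 4x4 invertible voxel-to-world matrix (mm)
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(shape = "integer", spacing = "numeric", affine = "matrix"))

setValidity("VoxelGrid", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be three entries >= 1")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive values (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be 4x4")
  d <- det(object@affine)
  if (!is.finite(d) || abs(d) < 1e-12)
    return("affine must be invertible")
  TRUE
})

#' Construct a VoxelGrid
#'
#' @param shape voxels per axis (length 3)
#' @param spacing mm per axis (length 3, or scalar recycled)
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by \code{spacing}
#' @return a \linkS4class{VoxelGrid}
#' @export
VoxelGrid <- function(shape, spacing = c(1, 1, 1), affine = NULL) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  new("VoxelGrid", shape = as.integer(shape), spacing = spacing,
      affine = affine)
}

setClass("BrainVolume",
  representation("VIRTUAL", values = "array", grid = "VoxelGrid"))

setValidity("BrainVolume", function(object) {
  if (length(dim(object@values)) != 3L)
    return("values must be a 3D array")
  if (!all(dim(object@values) == object@grid@shape))
    return("values shape must match grid shape")
  TRUE
})

#' PhaseVolume: 3D transceive phase in radians
#'
#' The reconstruction input. When \code{wrapped} is TRUE every value lies in
#' [0, 2*pi); unwrapped phase is unconstrained. The stored phase must be the
#' full transceive phase: the factor 2 in the conductivity conversion
#' embodies the transceive-phase assumption (the transmit phase is half the
#' transceive phase), so feeding half phase halves sigma.
#'
#' @slot values 3D numeric array, radians
#' @slot grid \linkS4class{VoxelGrid}
#' @slot wrapped logical flag
#' @exportClass PhaseVolume
setClass("PhaseVolume", contains = "BrainVolume",
  representation(wrapped = "logical"))

setValidity("PhaseVolume", function(object) {
  if (length(object@wrapped) != 1L) return("wrapped must be a single flag")
  if (isTRUE(object@wrapped)) {
    v <- object@values[is.finite(object@values)]
    if (length(v) && (min(v) < 0 || max(v) >= 2 * pi))
      return("wrapped phase must lie in [0, 2*pi)")
  }
  TRUE
})

#' @param values 3D numeric array of phase in radians
#' @param grid a \linkS4class{VoxelGrid}; defaults to unit 1 mm spacing
#' @param wrapped is the phase wrapped into [0, 2*pi)?
#' @return a \linkS4class{PhaseVolume}
#' @rdname PhaseVolume-class
#' @export
PhaseVolume <- function(values, grid = NULL, wrapped = FALSE) {
  values <- as.array(values)
  if (is.null(grid)) grid <- VoxelGrid(dim(values))
  new("PhaseVolume", values = values, grid = grid, wrapped = wrapped)
}

#' MagnitudeVolume: 3D nonnegative image amplitude
#'
#' Used by the kernel amplitude-similarity rule: neighbours whose amplitude
#' differs from the target voxel by more than the tolerance are excluded.
#'
#' @slot values 3D nonnegative numeric array
#' @slot grid \linkS4class{VoxelGrid}
#' @exportClass MagnitudeVolume
setClass("MagnitudeVolume", contains = "BrainVolume")

setValidity("MagnitudeVolume", function(object) {
  v <- object@values[is.finite(object@values)]
  if (length(v) && min(v) < 0) return("magnitude values must be >= 0")
  TRUE
})

#' @param values 3D nonnegative numeric array
#' @param grid a \linkS4class{VoxelGrid}
#' @return a \linkS4class{MagnitudeVolume}
#' @rdname MagnitudeVolume-class
#' @export
MagnitudeVolume <- function(values, grid = NULL) {
  values <- as.array(values)
  if (is.null(grid)) grid <- VoxelGrid(dim(values))
  new("MagnitudeVolume", values = values, grid = grid)
}

#' TissueLabelMap: integer tissue classes
#'
#' Codes: 0 background, 1 grey matter (GM), 2 white matter (WM), 3 CSF.
#' Kernels never mix voxels of different tissue classes, which is how
#' boundary artefacts are suppressed in the Laplacian.
#'
#' @slot values 3D integer array with codes 0..3
#' @slot grid \linkS4class{VoxelGrid}
#' @exportClass TissueLabelMap
setClass("TissueLabelMap", contains = "BrainVolume")

setValidity("TissueLabelMap", function(object) {
  v <- unique(as.vector(object@values))
  bad <- setdiff(v[!is.na(v)], TISSUE_CODES)
  if (length(bad))
    return(sprintf("unknown tissue code: %s", paste(bad, collapse = ", ")))
  TRUE
})

#' @param values 3D integer array of tissue codes (0 background, 1 GM, 2 WM,
#'   3 CSF)
#' @param grid a \linkS4class{VoxelGrid}
#' @return a \linkS4class{TissueLabelMap}
#' @rdname TissueLabelMap-class
#' @export
TissueLabelMap <- function(values, grid = NULL) {
  values <- as.array(values)
  storage.mode(values) <- "integer"
  if (is.null(grid)) grid <- VoxelGrid(dim(values))
  new("TissueLabelMap", values = values, grid = grid)
}

## ---------------------------------------------------------------------------
## Acquisition metadata, dynamic series, events
## ---------------------------------------------------------------------------

#' AcquisitionMeta: scan timing and field constants
#'
#' @slot larmorHz proton resonance frequency in Hz; the angular frequency
#'   omega = 2*pi*larmorHz is always derived, never stored
#' @slot mu0 magnetic permeability of free space (H/m)
#' @slot dynamicDuration seconds per dynamic frame
#' @slot dummyScans leading frames discarded at read time
#' @exportClass AcquisitionMeta
setClass("AcquisitionMeta",
  representation(larmorHz = "numeric", mu0 = "numeric",
                 dynamicDuration = "numeric", dummyScans = "integer"))

setValidity("AcquisitionMeta", function(object) {
  if (object@larmorHz <= 0) return("larmorHz must be > 0")
  if (object@mu0 <= 0) return("mu0 must be > 0")
  if (object@dynamicDuration <= 0) return("dynamicDuration must be > 0")
  if (object@dummyScans < 0L) return("dummyScans must be >= 0")
  TRUE
})

#' @param larmorHz Larmor frequency in Hz (default 3 T: 127.76 MHz)
#' @param dynamicDuration seconds per dynamic frame
#' @param dummyScans leading dummy frames to drop when reading a series
#' @param mu0 vacuum permeability, H/m
#' @return an \linkS4class{AcquisitionMeta}
#' @rdname AcquisitionMeta-class
#' @export
AcquisitionMeta <- function(larmorHz = DEFAULT_LARMOR_HZ,
                            dynamicDuration = 1.2, dummyScans = 0L,
                            mu0 = MU0) {
  new("AcquisitionMeta", larmorHz = as.numeric(larmorHz), mu0 = mu0,
      dynamicDuration = as.numeric(dynamicDuration),
      dummyScans = as.integer(dummyScans))
}

#' DynamicPhaseSeries: ordered 4D phase acquisition
#'
#' Frames share one \linkS4class{VoxelGrid}; \code{frames()} extracts
#' individual \linkS4class{PhaseVolume} objects. Frame midpoints (the
#' half-scan timing convention: the conductivity value of a dynamic is
#' assigned to the halfway point of its acquisition) are available through
#' \code{frameMidTimes()}.
#'
#' @slot values 4D numeric array (x, y, z, t), radians
#' @slot grid \linkS4class{VoxelGrid}
#' @slot wrapped logical, shared by all frames
#' @slot meta \linkS4class{AcquisitionMeta}
#' @exportClass DynamicPhaseSeries
setClass("DynamicPhaseSeries",
  representation(values = "array", grid = "VoxelGrid", wrapped = "logical",
                 meta = "AcquisitionMeta"))

setValidity("DynamicPhaseSeries", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L) return("values must be a 4D array")
  if (!all(d[1:3] == object@grid@shape))
    return("frame shape must match grid shape")
  if (d[4] < 1L) return("series must have at least one frame")
  TRUE
})

#' @param values 4D numeric array (x, y, z, t)
#' @param grid a \linkS4class{VoxelGrid}
#' @param meta an \linkS4class{AcquisitionMeta}
#' @param wrapped are frames wrapped into [0, 2*pi)?
#' @return a \linkS4class{DynamicPhaseSeries}
#' @rdname DynamicPhaseSeries-class
#' @export
DynamicPhaseSeries <- function(values, grid = NULL, meta = AcquisitionMeta(),
                               wrapped = FALSE) {
  values <- as.array(values)
  if (is.null(grid)) grid <- VoxelGrid(dim(values)[1:3])
  new("DynamicPhaseSeries", values = values, grid = grid, wrapped = wrapped,
      meta = meta)
}

#' StimulusSchedule: event table for a dynamic acquisition
#'
#' Nominal cycle onsets plus per-event jitter offsets; the actual stimulus
#' start is \code{onset + jitter}. Jittering onsets across cycles in 0.1 s
#' steps is what lets pooled samples tile a 100 ms grid even though frames
#' are over a second long.
#'
#' @slot onsets nominal stimulus start times, s, strictly increasing
#' @slot durations event durations, s, > 0
#' @slot jitters per-event jitter offsets, s
#' @slot contrast per-event stimulus contrast in [0, 1]
#' @exportClass StimulusSchedule
setClass("StimulusSchedule",
  representation(onsets = "numeric", durations = "numeric",
                 jitters = "numeric", contrast = "numeric"))

setValidity("StimulusSchedule", function(object) {
  n <- length(object@onsets)
  if (length(object@durations) != n || length(object@jitters) != n ||
      length(object@contrast) != n)
    return("onset, duration, jitter and contrast must have equal length")
  if (n >= 2L && any(diff(object@onsets) <= 0))
    return("onsets must be strictly increasing")
  if (n && any(object@durations <= 0)) return("durations must be > 0")
  if (n && (any(object@contrast < 0) || any(object@contrast > 1)))
    return("contrast must lie in [0, 1]")
  TRUE
})

#' @param onsets nominal stimulus start times (s)
#' @param durations event durations (s)
#' @param jitters jitter offsets (s); default 0
#' @param contrast stimulus contrasts in [0,1]; default 0.45
#' @return a \linkS4class{StimulusSchedule}
#' @rdname StimulusSchedule-class
#' @export
StimulusSchedule <- function(onsets, durations,
                             jitters = rep(0, length(onsets)),
                             contrast = rep(0.45, length(onsets))) {
  new("StimulusSchedule", onsets = as.numeric(onsets),
      durations = rep_len(as.numeric(durations), length(onsets)),
      jitters = rep_len(as.numeric(jitters), length(onsets)),
      contrast = rep_len(as.numeric(contrast), length(onsets)))
}

## ---------------------------------------------------------------------------
## Reconstruction types
## ---------------------------------------------------------------------------

#' KernelSpec: all Laplacian-kernel rules in one record
#'
#' Defaults follow the reconstruction this package implements: maximum
#' kernel box 9 x 9 x 6 voxels (the shorter axis on the slice direction),
#' neighbour amplitude within 10 percent of the target, one-sided parabola
#' fits accepted only when the correlation between fitted and measured phase
#' exceeds 0.7, and at least 6 surrounding voxels for a valid Laplacian.
#' Extents are symmetric reaches of floor(extent / 2) voxels per side.
#'
#' @slot maxExtent integer length-3 kernel box extents in voxels
#' @slot amplitudeTol relative magnitude difference for neighbour inclusion
#' @slot minCorr fit-acceptance correlation threshold, in (0, 1)
#' @slot minNeighbors minimum surrounding voxels for a valid Laplacian
#' @slot sigmaWindow plausibility window for conductivity, S/m
#' @exportClass KernelSpec
setClass("KernelSpec",
  representation(maxExtent = "integer", amplitudeTol = "numeric",
                 minCorr = "numeric", minNeighbors = "integer",
                 sigmaWindow = "numeric"))

setValidity("KernelSpec", function(object) {
  if (length(object@maxExtent) != 3L || any(object@maxExtent < 1L))
    return("maxExtent must be three entries >= 1")
  if (object@minCorr <= 0 || object@minCorr >= 1)
    return("minCorr must lie strictly between 0 and 1")
  if (object@amplitudeTol < 0) return("amplitudeTol must be >= 0")
  if (object@minNeighbors < 0L) return("minNeighbors must be >= 0")
  if (length(object@sigmaWindow) != 2L ||
      object@sigmaWindow[1] >= object@sigmaWindow[2])
    return("sigmaWindow must be an increasing pair (S/m)")
  TRUE
})

#' @param maxExtent kernel box extents in voxels (default c(9, 9, 6))
#' @param amplitudeTol relative amplitude tolerance (default 0.10)
#' @param minCorr fit-acceptance correlation (default 0.7)
#' @param minNeighbors minimum surrounding voxels (default 6)
#' @param sigmaWindow conductivity plausibility window in S/m
#'   (default c(-1, 5))
#' @return a \linkS4class{KernelSpec}
#' @rdname KernelSpec-class
#' @export
KernelSpec <- function(maxExtent = c(9L, 9L, 6L), amplitudeTol = 0.10,
                       minCorr = 0.7, minNeighbors = 6L,
                       sigmaWindow = c(-1, 5)) {
  new("KernelSpec", maxExtent = as.integer(maxExtent),
      amplitudeTol = amplitudeTol, minCorr = minCorr,
      minNeighbors = as.integer(minNeighbors),
      sigmaWindow = as.numeric(sigmaWindow))
}

#' LaplacianMap: voxelwise phase Laplacian with validity diagnostics
#'
#' @slot values 3D numeric array, rad/m^2, NA where no estimate
#' @slot valid 3D logical array; TRUE where all three axes were accepted and
#'   the neighbour count reached the minimum
#' @slot neighborCount 3D integer array of surrounding voxels in the kernel
#' @slot grid \linkS4class{VoxelGrid}
#' @exportClass LaplacianMap
setClass("LaplacianMap",
  representation(values = "array", valid = "array", neighborCount = "array",
                 grid = "VoxelGrid"))

setValidity("LaplacianMap", function(object) {
  if (!all(dim(object@values) == object@grid@shape) ||
      !all(dim(object@valid) == object@grid@shape) ||
      !all(dim(object@neighborCount) == object@grid@shape))
    return("all arrays must match the grid shape")
  if (any(!is.finite(object@values[object@valid])))
    return("values must be finite wherever valid")
  TRUE
})

#' ConductivityMap: voxelwise conductivity in S/m
#'
#' The reconstruction output and the functional signal carrier. Invalid
#' voxels hold NaN; valid values are restricted to the plausibility window
#' of the \linkS4class{KernelSpec} that produced them.
#'
#' @slot values 3D numeric array, S/m, NaN where invalid
#' @slot valid 3D logical array
#' @slot grid \linkS4class{VoxelGrid}
#' @exportClass ConductivityMap
setClass("ConductivityMap",
  representation(values = "array", valid = "array", grid = "VoxelGrid"))

setValidity("ConductivityMap", function(object) {
  if (!all(dim(object@values) == object@grid@shape) ||
      !all(dim(object@valid) == object@grid@shape))
    return("values and valid must match the grid shape")
  if (any(!is.finite(object@values[object@valid])))
    return("values must be finite wherever valid")
  TRUE
})

#' UnwrapResult: unwrapped phase plus region-growing diagnostics
#'
#' @slot phase the unwrapped \linkS4class{PhaseVolume} (wrapped = FALSE)
#' @slot nRegionsInitial number of connected interval regions before merging
#' @slot nMerges number of region merges performed
#' @exportClass UnwrapResult
setClass("UnwrapResult",
  representation(phase = "PhaseVolume", nRegionsInitial = "integer",
                 nMerges = "integer"))

## ---------------------------------------------------------------------------
## Response-function types
## ---------------------------------------------------------------------------

#' PooledTimecourse: jitter-pooled conductivity time course
#'
#' Times are relative to stimulus onset on a 100 ms grid (bin centres);
#' values are mean conductivity over the selected voxels; counts record how
#' many (cycle, frame) samples landed in each bin. Bins with zero count
#' carry NA values.
#'
#' @slot times bin-centre times, s, strictly increasing
#' @slot values mean conductivity per bin, S/m
#' @slot counts samples per bin
#' @exportClass PooledTimecourse
setClass("PooledTimecourse",
  representation(times = "numeric", values = "numeric", counts = "integer"))

setValidity("PooledTimecourse", function(object) {
  n <- length(object@times)
  if (length(object@values) != n || length(object@counts) != n)
    return("times, values and counts must have equal length")
  if (n >= 2L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (any(object@counts < 0L)) return("counts must be >= 0")
  if (any(object@counts == 0L & !is.na(object@values)))
    return("bins with zero count must carry NA values")
  TRUE
})

#' ResponseFunction: fitted conductivity response
#'
#' A causal curve on the pooled 100 ms grid expressed in an orthonormal
#' discrete Laguerre basis, with peak metrics. \code{fitted} includes the
#' pre-stimulus baseline; \code{peakAmplitude} is max(fitted) - baseline.
#'
#' @slot order number of Laguerre basis functions
#' @slot alpha discrete-Laguerre decay parameter in (0, 1)
#' @slot coefficients basis coefficients
#' @slot times grid of the fitted curve (t >= 0), s
#' @slot fitted fitted curve on \code{times}, S/m
#' @slot baseline pre-stimulus baseline conductivity, S/m
#' @slot peakAmplitude S/m above baseline
#' @slot peakTime s after stimulus onset
#' @slot returnToBaselineTime first post-peak time at <= 5 percent of peak, s
#' @exportClass ResponseFunction
setClass("ResponseFunction",
  representation(order = "integer", alpha = "numeric",
                 coefficients = "numeric", times = "numeric",
                 fitted = "numeric", baseline = "numeric",
                 peakAmplitude = "numeric", peakTime = "numeric",
                 returnToBaselineTime = "numeric"))

#' StimulusResponseFit: peak amplitude vs stimulus predictor
#'
#' Simple linear regression of response-function peak amplitudes on a
#' stimulus property (duration in s, or contrast level).
#'
#' @slot predictor predictor values
#' @slot peaks peak amplitudes, S/m
#' @slot slope regression slope
#' @slot intercept regression intercept
#' @slot rSquared coefficient of determination in [0, 1]
#' @exportClass StimulusResponseFit
setClass("StimulusResponseFit",
  representation(predictor = "numeric", peaks = "numeric", slope = "numeric",
                 intercept = "numeric", rSquared = "numeric"))

setValidity("StimulusResponseFit", function(object) {
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    return("rSquared must lie in [0, 1]")
  TRUE
})

## ---------------------------------------------------------------------------
## GLM types
## ---------------------------------------------------------------------------

#' DesignMatrix: GLM design for a conductivity series
#'
#' Task regressor (event boxcar convolved with the fitted conductivity
#' response function, sampled at frame mid-times), intercept, optional
#' linear drift. Non-intercept columns are mean-centred.
#'
#' @slot X numeric matrix, frames x columns, full column rank
#' @slot frameTimes frame mid-times, s
#' @exportClass DesignMatrix
setClass("DesignMatrix",
  representation(X = "matrix", frameTimes = "numeric"))

setValidity("DesignMatrix", function(object) {
  if (nrow(object@X) != length(object@frameTimes))
    return("X must have one row per frame time")
  # rank is checked at fit time: a degenerate (e.g. event-free) design is
  # representable, but not fittable
  TRUE
})

#' ActivationMaps: voxelwise GLM effect and t statistics
#'
#' @slot beta 3D effect-size array (S/m scaled)
#' @slot tmap 3D t-statistic array
#' @slot dof residual degrees of freedom (frames - rank(design))
#' @slot threshold display threshold for activation (default 2.2)
#' @slot valid 3D logical array of voxels entering the GLM
#' @slot grid \linkS4class{VoxelGrid}
#' @exportClass ActivationMaps
setClass("ActivationMaps",
  representation(beta = "array", tmap = "array", dof = "numeric",
                 threshold = "numeric", valid = "array", grid = "VoxelGrid"))

## ---------------------------------------------------------------------------
## Phantom types
## ---------------------------------------------------------------------------

#' PhantomSpec: ground-truth description for the synthetic forward model
#'
#' Compartments are painted in listed order (a later compartment overrides
#' earlier ones where they overlap, so structures can be embedded). Each
#' compartment is a list with elements \code{shape} ("sphere", "slab" or
#' "ellipsoid"), shape parameters (\code{center} and \code{radius} /
#' \code{semiaxes} in voxels, or \code{axis}/\code{from}/\code{to} for a
#' slab), \code{tissue} (a code or name), and \code{sigma} (S/m).
#'
#' The clean phase of a compartment with conductivity sigma is the quadratic
#' phi(r) = (mu0 * omega * sigma / 3) * |r - r0|^2 + offset, whose Laplacian
#' is exactly 2 * mu0 * omega * sigma, so ground truth lies inside the
#' parabolic-fit reconstruction's exactness class. \code{phaseCenter} is r0
#' in voxel coordinates and may lie outside the volume.
#'
#' @slot grid \linkS4class{VoxelGrid}
#' @slot compartments list of compartment descriptions
#' @slot noiseStd Gaussian phase-noise standard deviation, rad
#' @slot wrap wrap the phase into [0, 2*pi)?
#' @slot activation empty list, or list(roi = primitive, amplitude = S/m,
#'   peakTime = s, returnTime = s, onsetDelay = s, schedule =
#'   StimulusSchedule, nFrames = count)
#' @slot phaseCenter r0 in voxel coordinates (length 3)
#' @slot magnitudeLevels named amplitude per tissue (background, GM, WM, CSF)
#' @slot rippleAmp relative magnitude ripple amplitude
#' @slot smoothPhase use a Gaussian-bump phase instead of the quadratic
#'   (exercises non-exact fits)
#' @slot meta \linkS4class{AcquisitionMeta}
#' @slot seed integer seed for the noise stream
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(grid = "VoxelGrid", compartments = "list",
                 noiseStd = "numeric", wrap = "logical", activation = "list",
                 phaseCenter = "numeric", magnitudeLevels = "numeric",
                 rippleAmp = "numeric", smoothPhase = "logical",
                 meta = "AcquisitionMeta", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (!length(object@compartments))
    return("at least one compartment is required")
  for (cp in object@compartments) {
    if (is.null(cp$shape) || !cp$shape %in% c("sphere", "slab", "ellipsoid"))
      return("compartment shape must be sphere, slab or ellipsoid")
    if (is.null(cp$sigma) || cp$sigma < 0)
      return("compartment sigma must be >= 0")
  }
  if (object@noiseStd < 0) return("noiseStd must be >= 0")
  TRUE
})

#' PhantomTruth: ground truth retained by the generator
#'
#' @slot sigmaMap 3D conductivity truth, S/m (0 in background)
#' @slot activationMask 3D logical truth of the activated ROI
#' @slot responseTimes time grid of the injected response, s
#' @slot responseTruth injected response curve (S/m above baseline)
#' @slot phaseClean noiseless, unwrapped \linkS4class{PhaseVolume}
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(sigmaMap = "array", activationMask = "array",
                 responseTimes = "numeric", responseTruth = "numeric",
                 phaseClean = "PhaseVolume"))
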