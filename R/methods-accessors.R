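## Accessor and show methods. Kept together so the supported surface of each
## class is easy to audit.

#' @rdname accessors
#' @export
setMethod("values", "BrainVolume", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("values", "DynamicPhaseSeries", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("values", "LaplacianMap", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("values", "ConductivityMap", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("values", "PooledTimecourse", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("voxelGrid", "BrainVolume", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("voxelGrid", "DynamicPhaseSeries", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("voxelGrid", "LaplacianMap", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("voxelGrid", "ConductivityMap", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("voxelGrid", "ActivationMaps", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("spacing", "VoxelGrid", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("spacing", "BrainVolume", function(x) x@grid@spacing)

#' @rdname accessors
#' @export
setMethod("affine", "VoxelGrid", function(x) x@affine)

#' @rdname accessors
#' @export
setMethod("isWrapped", "PhaseVolume", function(x) x@wrapped)

#' @rdname accessors
#' @export
setMethod("isWrapped", "DynamicPhaseSeries", function(x) x@wrapped)

#' @rdname accessors
#' @export
setMethod("validMask", "LaplacianMap", function(x) x@valid)

#' @rdname accessors
#' @export
setMethod("validMask", "ConductivityMap", function(x) x@valid)

#' @rdname accessors
#' @export
setMethod("validMask", "ActivationMaps", function(x) x@valid)

#' @rdname accessors
#' @export
setMethod("neighborCount", "LaplacianMap", function(x) x@neighborCount)

#' @rdname accessors
#' @export
setMethod("nFrames", "DynamicPhaseSeries", function(x) dim(x@values)[4])

#' @rdname accessors
#' @export
setMethod("frames", "DynamicPhaseSeries", function(x) {
  lapply(seq_len(dim(x@values)[4]), function(t)
    PhaseVolume(x@values[, , , t, drop = TRUE], grid = x@grid,
                wrapped = x@wrapped))
})

#' @rdname accessors
#' @export
setMethod("frameMidTimes", "DynamicPhaseSeries", function(x) {
  dt <- x@meta@dynamicDuration
  (seq_len(dim(x@values)[4]) - 1) * dt + dt / 2
})

#' @rdname accessors
#' @export
setMethod("acquisitionMeta", "DynamicPhaseSeries", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("onsets", "StimulusSchedule", function(x) x@onsets)

#' @rdname accessors
#' @export
setMethod("durations", "StimulusSchedule", function(x) x@durations)

#' @rdname accessors
#' @export
setMethod("jitterOffsets", "StimulusSchedule", function(x) x@jitters)

#' @rdname accessors
#' @export
setMethod("eventContrasts", "StimulusSchedule", function(x) x@contrast)

#' @rdname accessors
#' @export
setMethod("length", "StimulusSchedule", function(x) length(x@onsets))

#' @rdname accessors
#' @export
setMethod("peakAmplitude", "ResponseFunction", function(x) x@peakAmplitude)

#' @rdname accessors
#' @export
setMethod("peakTime", "ResponseFunction", function(x) x@peakTime)

#' @rdname accessors
#' @export
setMethod("returnToBaselineTime", "ResponseFunction",
          function(x) x@returnToBaselineTime)

#' @rdname accessors
#' @export
setMethod("coef", "ResponseFunction", function(object, ...) object@coefficients)

#' @rdname accessors
#' @export
setMethod("fitted", "ResponseFunction", function(object, ...) object@fitted)

#' @rdname accessors
#' @export
setMethod("tMap", "ActivationMaps", function(x) x@tmap)

#' @rdname accessors
#' @export
setMethod("betaMap", "ActivationMaps", function(x) x@beta)

#' @rdname accessors
#' @export
setMethod("dof", "ActivationMaps", function(x) x@dof)

## show methods -------------------------------------------------------------

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %s voxels, spacing %s mm\n",
              paste(object@shape, collapse = " x "),
              paste(format(object@spacing, digits = 4), collapse = " x ")))
})

setMethod("show", "PhaseVolume", function(object) {
  v <- object@values[is.finite(object@values)]
  cat(sprintf("PhaseVolume: %s voxels, %s, range [%.3f, %.3f] rad\n",
              paste(dim(object@values), collapse = " x "),
              if (object@wrapped) "wrapped" else "unwrapped",
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "MagnitudeVolume", function(object) {
  cat(sprintf("MagnitudeVolume: %s voxels\n",
              paste(dim(object@values), collapse = " x ")))
})

setMethod("show", "TissueLabelMap", function(object) {
  tab <- table(factor(object@values, levels = TISSUE_CODES,
                      labels = names(TISSUE_CODES)))
  cat(sprintf("TissueLabelMap: %s voxels (%s)\n",
              paste(dim(object@values), collapse = " x "),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "DynamicPhaseSeries", function(object) {
  cat(sprintf(
    "DynamicPhaseSeries: %d frames of %s voxels, %.3g s per frame\n",
    dim(object@values)[4], paste(dim(object@values)[1:3], collapse = " x "),
    object@meta@dynamicDuration))
})

setMethod("show", "StimulusSchedule", function(object) {
  n <- length(object@onsets)
  cat(sprintf("StimulusSchedule: %d events", n))
  if (n)
    cat(sprintf(", onsets %.1f..%.1f s, jitter [%.1f, %.1f] s",
                min(object@onsets), max(object@onsets),
                min(object@jitters), max(object@jitters)))
  cat("\n")
})

setMethod("show", "KernelSpec", function(object) {
  cat(sprintf(
    "KernelSpec: box %s, amplitude tol %.2f, min corr %.2f, min neighbors %d\n",
    paste(object@maxExtent, collapse = " x "), object@amplitudeTol,
    object@minCorr, object@minNeighbors))
})

setMethod("show", "LaplacianMap", function(object) {
  cat(sprintf("LaplacianMap: %s voxels, %d valid (%.1f%%)\n",
              paste(dim(object@values), collapse = " x "),
              sum(object@valid),
              100 * mean(object@valid)))
})

setMethod("show", "ConductivityMap", function(object) {
  v <- object@values[object@valid]
  cat(sprintf("ConductivityMap: %s voxels, %d valid, mean %.3f S/m\n",
              paste(dim(object@values), collapse = " x "),
              sum(object@valid), if (length(v)) mean(v) else NA))
})

setMethod("show", "UnwrapResult", function(object) {
  cat(sprintf("UnwrapResult: %d initial regions, %d merges\n",
              object@nRegionsInitial, object@nMerges))
})

setMethod("show", "PooledTimecourse", function(object) {
  cat(sprintf(
    "PooledTimecourse: %d bins over [%.2f, %.2f] s, %d samples\n",
    length(object@times), min(object@times), max(object@times),
    sum(object@counts)))
})

setMethod("show", "ResponseFunction", function(object) {
  cat(sprintf(
    "ResponseFunction: order %d, alpha %.3f, peak %.4f S/m at %.2f s, back to baseline %.2f s\n",
    object@order, object@alpha, object@peakAmplitude, object@peakTime,
    object@returnToBaselineTime))
})

setMethod("show", "StimulusResponseFit", function(object) {
  cat(sprintf(
    "StimulusResponseFit: slope %.4f, intercept %.4f, R^2 %.4f (%d points)\n",
    object@slope, object@intercept, object@rSquared,
    length(object@predictor)))
})

setMethod("show", "ActivationMaps", function(object) {
  cat(sprintf(
    "ActivationMaps: %s voxels, dof %.0f, %d voxels with t > %.2f\n",
    paste(dim(object@tmap), collapse = " x "), object@dof,
    sum(object@tmap > object@threshold & object@valid, na.rm = TRUE),
    object@threshold))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %s voxels, %d compartments, noise %.3g rad%s%s\n",
    paste(object@grid@shape, collapse = " x "), length(object@compartments),
    object@noiseStd, if (object@wrap) ", wrapped" else "",
    if (length(object@activation)) ", with activation" else ""))
})
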