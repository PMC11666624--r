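#' Accessors for funCI containers
#'
#' Small generic accessor family: slot access is internal, these are the
#' supported surface.
#'
#' @param x a funCI object
#' @param object a funCI object (for \code{show})
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' @rdname accessors
#' @export
setGeneric("isWrapped", function(x) standardGeneric("isWrapped"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("neighborCount", function(x) standardGeneric("neighborCount"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("frameMidTimes", function(x) standardGeneric("frameMidTimes"))

#' @rdname accessors
#' @export
setGeneric("acquisitionMeta", function(x) standardGeneric("acquisitionMeta"))

#' @rdname accessors
#' @export
setGeneric("onsets", function(x) standardGeneric("onsets"))

#' @rdname accessors
#' @export
setGeneric("durations", function(x) standardGeneric("durations"))

#' @rdname accessors
#' @export
setGeneric("jitterOffsets", function(x) standardGeneric("jitterOffsets"))

#' @rdname accessors
#' @export
setGeneric("eventContrasts", function(x) standardGeneric("eventContrasts"))

#' @rdname accessors
#' @export
setGeneric("peakAmplitude", function(x) standardGeneric("peakAmplitude"))

#' @rdname accessors
#' @export
setGeneric("peakTime", function(x) standardGeneric("peakTime"))

#' @rdname accessors
#' @export
setGeneric("returnToBaselineTime",
           function(x) standardGeneric("returnToBaselineTime"))

#' @rdname accessors
#' @export
setGeneric("tMap", function(x) standardGeneric("tMap"))

#' @rdname accessors
#' @export
setGeneric("betaMap", function(x) standardGeneric("betaMap"))

#' @rdname accessors
#' @export
setGeneric("dof", function(x) standardGeneric("dof"))
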