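## NIfTI, events-TSV and YAML plumbing. All volumes travel as NIfTI-1
## (.nii/.nii.gz) through RNifti; phase is stored in radians internally and
## any scanner scaling is undone at read time via the `scale`/`offset`
## arguments (on top of the NIfTI header slope/intercept, which RNifti
## already applies).

gridFromNifti <- function(img) {
  d <- dim(img)[1:3]
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  # spacing from the affine column norms: the header pixdim field is not
  # guaranteed to track a stored sform
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(sp <= 0)) sp <- abs(as.numeric(RNifti::pixdim(img)[1:3]))
  VoxelGrid(shape = d, spacing = sp, affine = aff)
}

#' Rebase phase values into [0, 2*pi)
#'
#' Each voxel changes by an exact multiple of 2*pi; the operation is
#' idempotent.
#'
#' @param values numeric array or vector of phase in radians
#' @return values wrapped into [0, 2*pi)
#' @export
rebasePhase <- function(values) {
  out <- values - 2 * pi * floor(values / (2 * pi))
  # guard against values == 2*pi after rounding
  out[out >= 2 * pi] <- 0
  out
}

#' Read a 3D NIfTI volume as a typed container
#'
#' Phase volumes are detected as wrapped when all finite values lie in
#' [0, 2*pi) or in (-pi, pi]; the latter are rebased to [0, 2*pi) (an exact
#' multiple of 2*pi per voxel). Label volumes must only contain the tissue
#' codes 0 (background), 1 (GM), 2 (WM), 3 (CSF).
#'
#' @param path path to a 3D NIfTI file
#' @param kind one of "phase", "magnitude", "labels"
#' @param scale,offset optional affine conversion applied to phase values
#'   (radians = scale * stored + offset) for scanner exports not already in
#'   radians
#' @return a \linkS4class{PhaseVolume}, \linkS4class{MagnitudeVolume} or
#'   \linkS4class{TissueLabelMap}
#' @export
readVolume <- function(path, kind = c("phase", "magnitude", "labels"),
                       scale = 1, offset = 0) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path)
  grid <- gridFromNifti(img)
  vals <- array(as.numeric(img), dim = dim(img))
  switch(kind,
    phase = {
      vals <- scale * vals + offset
      fin <- vals[is.finite(vals)]
      if (length(fin) && min(fin) >= 0 && max(fin) < 2 * pi) {
        PhaseVolume(vals, grid, wrapped = TRUE)
      } else if (length(fin) && min(fin) > -pi && max(fin) <= pi) {
        PhaseVolume(rebasePhase(vals), grid, wrapped = TRUE)
      } else {
        PhaseVolume(vals, grid, wrapped = FALSE)
      }
    },
    magnitude = MagnitudeVolume(vals, grid),
    labels = TissueLabelMap(round(vals), grid))
}

#' Write a volume container to NIfTI
#'
#' Values, shape, spacing and affine survive a write/read round trip
#' exactly (data are written as float64).
#'
#' @param vol a \linkS4class{PhaseVolume}, \linkS4class{MagnitudeVolume} or
#'   \linkS4class{TissueLabelMap}
#' @param path output .nii or .nii.gz path
#' @return the path, invisibly
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "BrainVolume"))
  img <- RNifti::asNifti(vol@values, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(vol@grid@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a dynamic phase series
#'
#' Accepts a single 4D NIfTI or an ordered vector of 3D NIfTI paths. Dummy
#' frames (\code{meta@dummyScans}) are dropped here, at read time, so timing
#' downstream has a single place of truth. Frames must share one grid.
#'
#' @param paths a 4D NIfTI path or character vector of 3D paths in
#'   acquisition order
#' @param meta an \linkS4class{AcquisitionMeta} carrying the dynamic frame
#'   duration and dummy-scan count
#' @param scale,offset phase conversion as in \code{\link{readVolume}}
#' @return a \linkS4class{DynamicPhaseSeries}
#' @export
readSeries <- function(paths, meta = AcquisitionMeta(), scale = 1,
                       offset = 0) {
  if (length(paths) == 1L) {
    if (!file.exists(paths)) stop("file not found: ", paths)
    img <- RNifti::readNifti(paths)
    if (length(dim(img)) != 4L)
      stop("expected a 4D volume, got ", length(dim(img)), "D")
    vals <- array(as.numeric(img), dim = dim(img))
    grid <- gridFromNifti(img)
  } else {
    vols <- lapply(paths, readVolume, kind = "phase")
    grid <- vols[[1]]@grid
    for (v in vols[-1]) {
      if (!all(v@grid@shape == grid@shape) ||
          max(abs(v@grid@spacing - grid@spacing)) > 1e-6)
        stop("inconsistent grids across frames")
    }
    vals <- array(0, dim = c(grid@shape, length(vols)))
    for (t in seq_along(vols)) vals[, , , t] <- vols[[t]]@values
  }
  vals <- scale * vals + offset
  nd <- meta@dummyScans
  if (nd >= dim(vals)[4])
    stop("dummyScans (", nd, ") leaves no frames")
  if (nd > 0L) vals <- vals[, , , -(seq_len(nd)), drop = FALSE]
  fin <- vals[is.finite(vals)]
  wrapped <- length(fin) > 0 && min(fin) >= 0 && max(fin) < 2 * pi
  DynamicPhaseSeries(vals, grid = grid, meta = meta, wrapped = wrapped)
}

#' Write a dynamic phase series as 4D NIfTI
#'
#' @param series a \linkS4class{DynamicPhaseSeries}
#' @param path output path
#' @return the path, invisibly
#' @export
writeSeries <- function(series, path) {
  stopifnot(is(series, "DynamicPhaseSeries"))
  img <- RNifti::asNifti(series@values, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(series@grid@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a stimulus-event table
#'
#' Tab-separated with a header row: onset, duration, jitter, contrast
#' (seconds, seconds, seconds, unitless), one row per stimulus cycle —
#' a BIDS-events-like dialect. An empty table yields an empty (valid)
#' schedule that downstream operations reject.
#'
#' @param path TSV path
#' @return a \linkS4class{StimulusSchedule}
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE)
  need <- c("onset", "duration", "jitter", "contrast")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("events table missing column(s): ", paste(miss, collapse = ", "))
  StimulusSchedule(onsets = tab$onset, durations = tab$duration,
                   jitters = tab$jitter, contrast = tab$contrast)
}

#' Write a stimulus schedule as an events TSV
#'
#' @param schedule a \linkS4class{StimulusSchedule}
#' @param path output TSV path
#' @return the path, invisibly
#' @export
writeEvents <- function(schedule, path) {
  tab <- data.frame(onset = schedule@onsets, duration = schedule@durations,
                    jitter = schedule@jitters, contrast = schedule@contrast)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read acquisition metadata from YAML
#'
#' Recognised keys: \code{larmor_hz}, \code{dynamic_duration},
#' \code{dummy_scans}, \code{mu0}. Unknown keys are rejected.
#'
#' @param path YAML path
#' @return an \linkS4class{AcquisitionMeta}
#' @export
readAcquisitionMeta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("larmor_hz", "dynamic_duration", "dummy_scans", "mu0")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown acquisition key(s): ", paste(bad, collapse = ", "))
  AcquisitionMeta(
    larmorHz = if (!is.null(y$larmor_hz)) y$larmor_hz else DEFAULT_LARMOR_HZ,
    dynamicDuration = if (!is.null(y$dynamic_duration)) y$dynamic_duration else 1.2,
    dummyScans = if (!is.null(y$dummy_scans)) y$dummy_scans else 0L,
    mu0 = if (!is.null(y$mu0)) y$mu0 else MU0)
}
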