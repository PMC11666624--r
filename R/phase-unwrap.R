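#' Region-growing 3D phase unwrapping
#'
#' Divides the [0, 2*pi) interval into six sub-intervals, labels 6-connected
#' regions of voxels falling in the same sub-interval, then iteratively
#' merges the pair of regions sharing the largest border, adding to one side
#' the multiple of 2*pi that minimises the boundary discontinuity (the
#' median wrapped difference across the shared faces). After merging, each
#' connected mask component receives the global 2*pi multiple that minimises
#' its mean absolute phase. Ties on border size are broken
#' largest-region-index-first.
#'
#' The voxelwise difference between output and input is always an exact
#' multiple of 2*pi. Phase outside the mask is returned unchanged.
#'
#' @param phase a wrapped \linkS4class{PhaseVolume}
#' @param mask 3D logical array, nonempty
#' @param bypass accept externally unwrapped phase: the input is returned
#'   (flagged unwrapped) without modification
#' @return an \linkS4class{UnwrapResult}
#' @export
unwrapPhase <- function(phase, mask, bypass = FALSE) {
  stopifnot(is(phase, "PhaseVolume"))
  if (bypass) {
    out <- phase
    out@wrapped <- FALSE
    return(new("UnwrapResult", phase = out, nRegionsInitial = 0L,
               nMerges = 0L))
  }
  if (!isWrapped(phase))
    stop("input phase is not wrapped; use bypass = TRUE to pass it through")
  mask <- array(as.logical(mask), dim = dim(phase@values))
  if (!any(mask)) stop("empty mask")
  v <- phase@values
  if (all(!is.finite(v[mask]))) stop("all-NaN input inside mask")
  if (any(!is.finite(v[mask]))) stop("non-finite phase inside mask")

  dm <- dim(v)
  cls <- array(0L, dm)
  cls[mask] <- pmin(floor(v[mask] / (2 * pi / 6)), 5) + 1L
  lab <- array(cpp_label_components(as.integer(cls), as.integer(dm)), dm)
  nreg <- max(lab)

  faces <- cpp_region_faces(as.integer(lab), as.numeric(v), as.integer(dm))
  fa <- faces$a; fb <- faces$b; pa <- faces$pa; pb <- faces$pb

  grp <- seq_len(nreg)        # region -> current group id
  offs <- numeric(nreg)       # accumulated 2*pi multiples per region
  nmerge <- 0L
  while (length(fa)) {
    ga <- grp[fa]; gb <- grp[fb]
    keep <- ga != gb
    if (!any(keep)) break
    ga <- ga[keep]; gb <- gb[keep]
    dpa <- pa[keep] + offs[fa[keep]]
    dpb <- pb[keep] + offs[fb[keep]]
    lo <- pmin(ga, gb); hi <- pmax(ga, gb)
    key <- lo * (nreg + 1) + hi
    cnt <- table(key)
    best <- as.numeric(names(cnt))
    o <- order(as.integer(cnt), best %% (nreg + 1), best %/% (nreg + 1),
               decreasing = TRUE)
    bk <- best[o[1]]
    gA <- bk %/% (nreg + 1); gB <- bk %% (nreg + 1)
    sel <- (ga == gA & gb == gB) | (ga == gB & gb == gA)
    d <- ifelse(ga[sel] == gA, dpa[sel] - dpb[sel], dpb[sel] - dpa[sel])
    k <- round(stats::median(d) / (2 * pi))
    inB <- grp == gB
    offs[inB] <- offs[inB] + 2 * pi * k
    grp[inB] <- gA
    nmerge <- nmerge + 1L
  }

  out <- v
  out[mask] <- v[mask] + offs[lab[mask]]

  # global offset per connected component: the 2*pi multiple minimising the
  # mean absolute phase
  for (g in unique(grp)) {
    sel <- mask & array(grp[pmax(lab, 1L)] == g, dm) & lab > 0
    vals <- out[sel]
    if (!length(vals)) next
    ks <- seq(floor(min(vals) / (2 * pi)), ceiling(max(vals) / (2 * pi)))
    mads <- vapply(ks, function(k) mean(abs(vals - 2 * pi * k)), numeric(1))
    out[sel] <- vals - 2 * pi * ks[which.min(mads)]
  }

  new("UnwrapResult",
      phase = PhaseVolume(out, grid = phase@grid, wrapped = FALSE),
      nRegionsInitial = as.integer(nreg), nMerges = nmerge)
}
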