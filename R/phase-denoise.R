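#' Diffusion parameters for adaptive phase denoising
#'
#' Defaults follow the reconstruction pipeline: 400 explicit iterations with
#' integration constant 0.18 and a sigmoid diffusivity
#' g(|grad phi|) = 1 / (1 + exp((|grad phi| - kappa) / slope)). The gradient
#' scale kappa defaults to twice the median absolute forward difference
#' inside the mask (data-driven), and the sigmoid slope to kappa / 4.
#'
#' @param iterations number of explicit time steps (>= 0)
#' @param dt integration constant (explicit time step), in (0, 0.25]
#' @param kappa gradient scale in rad/voxel, or NA for the adaptive default
#' @param sigmoidSlope sigmoid slope, or NA for kappa / 4
#' @return a list of class "DiffusionParams"
#' @export
DiffusionParams <- function(iterations = 400L, dt = 0.18, kappa = NA_real_,
                            sigmoidSlope = NA_real_) {
  if (iterations < 0) stop("iterations must be >= 0")
  if (dt <= 0 || dt > 0.25)
    stop("dt must lie in (0, 0.25] for explicit-scheme stability")
  if (!is.na(kappa) && kappa <= 0) stop("kappa must be > 0")
  structure(list(iterations = as.integer(iterations), dt = dt,
                 diffusivity = "sigmoid", kappa = kappa,
                 sigmoidSlope = sigmoidSlope),
            class = "DiffusionParams")
}

#' Adaptive nonlinear phase denoising
#'
#' Perona-Malik-type anisotropic diffusion with a sigmoid conductance,
#' explicit time stepping, masked updates and reflecting (no-flux)
#' boundaries, applied to unwrapped phase. Flux is only exchanged between
#' pairs of in-mask voxels, so the mean phase over the mask is conserved.
#' Gradients well below kappa diffuse freely (noise removal); gradients well
#' above kappa see near-zero conductance (edge preservation).
#'
#' @param phase an unwrapped \linkS4class{PhaseVolume}, finite inside mask
#' @param mask 3D logical array
#' @param params a \code{\link{DiffusionParams}}
#' @return the denoised \linkS4class{PhaseVolume} (unchanged outside mask;
#'   returned as-is when \code{iterations} is 0)
#' @export
denoisePhase <- function(phase, mask, params = DiffusionParams()) {
  stopifnot(is(phase, "PhaseVolume"), inherits(params, "DiffusionParams"))
  if (isWrapped(phase)) stop("phase must be unwrapped before denoising")
  mask <- array(as.logical(mask), dim = dim(phase@values))
  v <- phase@values
  if (any(!is.finite(v[mask]))) stop("non-finite phase inside mask")
  if (params$iterations == 0L) return(phase)

  kappa <- params$kappa
  if (is.na(kappa)) {
    # adaptive scale: 2 x median absolute forward difference inside the mask
    fd <- c(diffsInMask(v, mask, 1L), diffsInMask(v, mask, 2L),
            diffsInMask(v, mask, 3L))
    kappa <- 2 * stats::median(abs(fd))
    if (!is.finite(kappa) || kappa <= 0) kappa <- 1e-6
  }
  slope <- params$sigmoidSlope
  if (is.na(slope)) slope <- kappa / 4

  out <- cpp_diffuse(as.numeric(v), as.logical(mask),
                     as.integer(dim(v)), params$iterations, params$dt,
                     kappa, slope)
  PhaseVolume(array(out, dim(v)), grid = phase@grid, wrapped = FALSE)
}

# forward differences along one axis, both endpoints inside the mask
diffsInMask <- function(v, mask, axis) {
  d <- dim(v)
  n <- d[axis]
  if (n < 2L) return(numeric(0))
  idx1 <- switch(axis,
    list(1:(d[1] - 1), 1:d[2], 1:d[3]),
    list(1:d[1], 1:(d[2] - 1), 1:d[3]),
    list(1:d[1], 1:d[2], 1:(d[3] - 1)))
  idx2 <- switch(axis,
    list(2:d[1], 1:d[2], 1:d[3]),
    list(1:d[1], 2:d[2], 1:d[3]),
    list(1:d[1], 1:d[2], 2:d[3]))
  a <- v[idx1[[1]], idx1[[2]], idx1[[3]], drop = FALSE]
  b <- v[idx2[[1]], idx2[[2]], idx2[[3]], drop = FALSE]
  ma <- mask[idx1[[1]], idx1[[2]], idx1[[3]], drop = FALSE]
  mb <- mask[idx2[[1]], idx2[[2]], idx2[[3]], drop = FALSE]
  (b - a)[ma & mb]
}
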