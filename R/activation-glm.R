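#' Build a GLM design for a conductivity series
#'
#' The task regressor is the stimulus boxcar (unit height over each event's
#' duration, at the jittered onsets) convolved with the fitted conductivity
#' response function on a fine grid, then sampled at the frame mid-times.
#' Non-intercept columns are mean-centred. An optional linear drift column
#' is available (off by default).
#'
#' @param schedule a \linkS4class{StimulusSchedule}; events must fall
#'   inside the frame-time range
#' @param rf a fitted \linkS4class{ResponseFunction} (its baseline is
#'   removed before convolution)
#' @param frameTimes increasing frame mid-times, s
#' @param drift add a linear drift column?
#' @param binWidth convolution grid step, s (default 0.1, the pooled grid)
#' @return a \linkS4class{DesignMatrix}
#' @export
buildDesign <- function(schedule, rf, frameTimes, drift = FALSE,
                        binWidth = 0.1) {
  stopifnot(is(rf, "ResponseFunction"))
  frameTimes <- as.numeric(frameTimes)
  if (is.unsorted(frameTimes, strictly = TRUE))
    stop("frameTimes must be strictly increasing")
  tMax <- max(frameTimes)
  onsetsAct <- schedule@onsets + schedule@jitters
  if (length(onsetsAct) && (min(onsetsAct) < 0 || max(onsetsAct) > tMax))
    stop("events outside the time range of the series")

  grid <- seq(0, tMax + binWidth, by = binWidth)
  box <- numeric(length(grid))
  for (e in seq_along(onsetsAct)) {
    on <- onsetsAct[e]
    box[grid >= on & grid < on + schedule@durations[e]] <- 1
  }
  h <- rf@fitted - rf@baseline
  dense <- if (any(box != 0)) {
    full <- stats::convolve(box, rev(h), type = "open")
    full[seq_along(grid)]
  } else numeric(length(grid))
  task <- stats::approx(grid, dense, xout = frameTimes, rule = 2)$y

  X <- cbind(task = task - mean(task), intercept = 1)
  if (drift) {
    dr <- frameTimes - mean(frameTimes)
    X <- cbind(X, drift = dr / max(abs(dr)))
  }
  new("DesignMatrix", X = X, frameTimes = frameTimes)
}

#' Voxelwise GLM on a conductivity series
#'
#' Ordinary least squares per voxel of the framewise conductivity on the
#' design; reports the task effect (beta) and its t statistic. Voxels valid
#' in fewer than \code{minValidFrac} of the frames are excluded (NaN); for
#' the remainder the fit uses exactly the frames where the voxel is valid.
#'
#' @param maps list of \linkS4class{ConductivityMap}, one per frame; at
#'   least columns + 2 frames
#' @param design a \linkS4class{DesignMatrix}
#' @param minValidFrac minimum fraction of valid frames per voxel
#' @param threshold display threshold stored with the maps (default 2.2)
#' @return an \linkS4class{ActivationMaps}
#' @export
fitActivationGlm <- function(maps, design, minValidFrac = 0.9,
                             threshold = 2.2) {
  stopifnot(is(design, "DesignMatrix"))
  X <- design@X
  Tn <- length(maps)
  if (Tn != nrow(X)) stop("one design row per frame is required")
  rk <- qr(X)$rank
  if (rk < ncol(X)) stop("rank-deficient design")
  if (Tn < ncol(X) + 2) stop("need at least columns + 2 frames")
  dm <- dim(maps[[1]]@values)
  task <- which(colnames(X) == "task")

  Y <- vapply(maps, function(m) as.numeric(m@values), numeric(prod(dm)))
  Y <- t(matrix(Y, nrow = prod(dm)))           # frames x voxels
  nValid <- colSums(is.finite(Y))
  use <- nValid >= ceiling(minValidFrac * Tn) & nValid >= ncol(X) + 2

  beta <- rep(NaN, prod(dm))
  tval <- rep(NaN, prod(dm))
  dofFull <- Tn - rk

  full <- use & nValid == Tn
  if (any(full)) {
    qx <- qr(X)
    cf <- qr.coef(qx, Y[, full, drop = FALSE])
    res <- Y[, full, drop = FALSE] - X %*% cf
    s2 <- colSums(res^2) / dofFull
    xtxInv <- chol2inv(chol(crossprod(X)))[task, task]
    beta[full] <- cf[task, ]
    se <- sqrt(s2 * xtxInv)
    tval[full] <- cf[task, ] / se
  }
  partial <- which(use & nValid < Tn)
  for (v in partial) {
    ok <- is.finite(Y[, v])
    Xv <- X[ok, , drop = FALSE]
    if (qr(Xv)$rank < ncol(X)) next
    fit <- stats::lm.fit(Xv, Y[ok, v])
    dofV <- sum(ok) - ncol(X)
    if (dofV < 1) next
    s2 <- sum(fit$residuals^2) / dofV
    xtxInv <- chol2inv(chol(crossprod(Xv)))[task, task]
    beta[v] <- fit$coefficients[task]
    tval[v] <- fit$coefficients[task] / sqrt(s2 * xtxInv)
  }

  new("ActivationMaps", beta = array(beta, dm), tmap = array(tval, dm),
      dof = dofFull, threshold = threshold,
      valid = array(use & is.finite(tval), dm), grid = maps[[1]]@grid)
}

#' Threshold an activation map
#'
#' The default is the raw display threshold t > 2.2 with no multiple-
#' comparison correction; an optional Benjamini-Hochberg FDR mode is
#' provided (off by default).
#'
#' @param maps an \linkS4class{ActivationMaps}
#' @param threshold t threshold (defaults to the value stored in
#'   \code{maps})
#' @param fdr use Benjamini-Hochberg FDR instead of a raw t threshold?
#' @param fdrLevel FDR level when \code{fdr} is TRUE
#' @return 3D logical activation mask
#' @export
thresholdMap <- function(maps, threshold = maps@threshold, fdr = FALSE,
                         fdrLevel = 0.05) {
  stopifnot(is(maps, "ActivationMaps"))
  if (fdr) {
    p <- stats::pt(maps@tmap[maps@valid], df = maps@dof, lower.tail = FALSE)
    padj <- stats::p.adjust(p, method = "BH")
    out <- array(FALSE, dim(maps@tmap))
    out[maps@valid] <- padj < fdrLevel
    return(out)
  }
  out <- maps@tmap > threshold & maps@valid
  out[!is.finite(maps@tmap)] <- FALSE
  out
}
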