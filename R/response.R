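#' Select stimulus-responsive voxels within an ROI
#'
#' Keeps ROI voxels whose conductivity at the first post-onset frame of the
#' first stimulus cycle exceeds that voxel's OFF baseline. The baseline is
#' the mean over frames in the last \code{baselineFrac} of the interval
#' preceding the first onset (frame times use the half-scan convention:
#' each frame's value sits at the midpoint of its acquisition).
#'
#' @param maps list of \linkS4class{ConductivityMap} (one per frame)
#' @param schedule a nonempty \linkS4class{StimulusSchedule}
#' @param roi 3D logical array, nonempty
#' @param meta an \linkS4class{AcquisitionMeta} (frame duration)
#' @param baselineFrac fraction of the pre-onset interval used as OFF
#'   baseline (default 0.25)
#' @return integer matrix (n x 3) of selected voxel indices. The frames
#'   that entered the comparison are attached as attribute
#'   \code{"selectionFrames"}: passing them to
#'   \code{\link{poolJittered}}'s \code{excludeFrames} keeps the pooled
#'   time course free of selection-induced bias (the selected voxels'
#'   noise at those frames is conditioned positive/negative by the
#'   selection itself)
#' @export
selectResponseVoxels <- function(maps, schedule, roi,
                                 meta = AcquisitionMeta(),
                                 baselineFrac = 0.25) {
  if (!length(schedule@onsets)) stop("empty stimulus schedule")
  roi <- array(as.logical(roi), dim = dim(maps[[1]]@values))
  if (!any(roi)) stop("empty ROI")
  dt <- meta@dynamicDuration
  tmid <- (seq_along(maps) - 1) * dt + dt / 2
  on1 <- schedule@onsets[1] + schedule@jitters[1]
  onFrame <- which(tmid > on1)[1]
  if (is.na(onFrame)) stop("no post-onset frames available")
  base0 <- on1 * (1 - baselineFrac)
  baseFrames <- which(tmid >= base0 & tmid < on1)
  if (!length(baseFrames)) baseFrames <- which(tmid < on1)
  if (!length(baseFrames)) stop("no pre-onset frames available")

  idx <- which(roi, arr.ind = TRUE)
  onVals <- maps[[onFrame]]@values[idx]
  baseVals <- vapply(baseFrames, function(f) maps[[f]]@values[idx],
                     numeric(nrow(idx)))
  baseVals <- matrix(baseVals, nrow = nrow(idx))
  baseMean <- rowMeans(baseVals, na.rm = TRUE)
  sel <- is.finite(onVals) & is.finite(baseMean) & onVals > baseMean
  out <- idx[sel, , drop = FALSE]
  attr(out, "selectionFrames") <- sort(unique(c(baseFrames, onFrame)))
  out
}

#' Pool a jittered dynamic series onto a 100 ms grid
#'
#' Each frame of each stimulus cycle is mapped to
#' t = frame midpoint - (cycle onset + jitter); the mean conductivity over
#' the selected voxels (valid voxels only, per frame) is then binned onto a
#' centre-aligned grid of width \code{binWidth} (ties assigned to the
#' earlier bin). Because onsets are jittered in 0.1 s steps across cycles,
#' pooled samples tile a grid much finer than the frame duration.
#'
#' @param maps list of \linkS4class{ConductivityMap}
#' @param schedule a \linkS4class{StimulusSchedule}
#' @param voxels integer matrix (n x 3) of voxel indices, nonempty
#' @param meta an \linkS4class{AcquisitionMeta}
#' @param window times (s, relative to onset) retained, default
#'   c(-2, 13.4) (just under one duty-cycle period, so every frame is used
#'   once)
#' @param binWidth pooled bin width in seconds (default 0.1)
#' @param excludeFrames frame indices left out of pooling — typically the
#'   \code{"selectionFrames"} attribute of
#'   \code{\link{selectResponseVoxels}}, whose noise is biased by the
#'   selection conditioning
#' @param weighting "invvar" (default) combines voxels by inverse-variance
#'   weights estimated from each voxel's temporal variance — voxels with
#'   short kernel rows are several times noisier than interior ones, and
#'   down-weighting them sharpens the pooled course considerably;
#'   "uniform" is the plain mean
#' @return a \linkS4class{PooledTimecourse}
#' @export
poolJittered <- function(maps, schedule, voxels, meta = AcquisitionMeta(),
                         window = c(-2, 13.4), binWidth = 0.1,
                         excludeFrames = integer(0),
                         weighting = c("invvar", "uniform")) {
  weighting <- match.arg(weighting)
  if (is.null(dim(voxels))) voxels <- matrix(voxels, ncol = 3)
  if (!nrow(voxels)) stop("empty voxel set")
  dt <- meta@dynamicDuration
  tmid <- (seq_along(maps) - 1) * dt + dt / 2

  M <- vapply(maps, function(m) m@values[voxels], numeric(nrow(voxels)))
  M <- matrix(M, nrow = nrow(voxels))          # voxels x frames
  if (weighting == "invvar" && nrow(M) > 1) {
    vv <- apply(M, 1, stats::var, na.rm = TRUE)
    vv[!is.finite(vv)] <- Inf
    w <- 1 / pmax(vv, 1e-12)
  } else {
    w <- rep(1, nrow(M))
  }
  frameMean <- vapply(seq_len(ncol(M)), function(t) {
    ok <- is.finite(M[, t]) & w > 0
    if (!any(ok)) NA_real_
    else sum(M[ok, t] * w[ok]) / sum(w[ok])
  }, numeric(1))
  if (length(excludeFrames)) frameMean[excludeFrames] <- NA_real_

  onsetsAct <- schedule@onsets + schedule@jitters
  tRel <- rep(tmid, times = length(onsetsAct)) -
    rep(onsetsAct, each = length(tmid))
  val <- rep(frameMean, times = length(onsetsAct))
  keep <- tRel >= window[1] & tRel <= window[2] & !is.na(val)
  tRel <- tRel[keep]; val <- val[keep]
  if (!length(tRel)) stop("no samples fall inside the pooling window")

  bin <- ceiling(tRel / binWidth - 0.5)   # nearest centre, ties to earlier
  rng <- seq(min(bin), max(bin))
  counts <- integer(length(rng))
  sums <- numeric(length(rng))
  pos <- match(bin, rng)
  for (i in seq_along(pos)) {
    counts[pos[i]] <- counts[pos[i]] + 1L
    sums[pos[i]] <- sums[pos[i]] + val[i]
  }
  vals <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
  new("PooledTimecourse", times = rng * binWidth, values = vals,
      counts = counts)
}

#' Orthonormal discrete Laguerre basis
#'
#' Discrete Laguerre functions of decay parameter alpha evaluated at sample
#' indices 0..N-1, generated by the stable recurrence
#' \deqn{l_j(n) = \sqrt{\alpha}\, l_j(n-1) + \sqrt{\alpha}\, l_{j-1}(n) - l_{j-1}(n-1)}
#' with \eqn{l_0(n) = \sqrt{1-\alpha}\,\alpha^{n/2}}. Columns are
#' orthonormal over the discrete index (exactly so as N grows; the residual
#' tail is of order alpha^N).
#'
#' @param order number of basis functions (>= 1)
#' @param alpha decay parameter, strictly in (0, 1)
#' @param times time grid (only its length is used; kept in the signature
#'   so callers can pass the pooled grid)
#' @return matrix with length(times) rows and \code{order} columns
#' @export
laguerreBasis <- function(order, alpha, times) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  if (order < 1) stop("order must be >= 1")
  N <- length(times)
  B <- matrix(0, N, order)
  sa <- sqrt(alpha)
  B[, 1] <- sqrt(1 - alpha) * sa^(seq_len(N) - 1)
  if (order > 1) {
    for (j in 2:order) {
      B[1, j] <- sa * B[1, j - 1]
      for (n in 2:N)
        B[n, j] <- sa * B[n - 1, j] + sa * B[n, j - 1] - B[n - 1, j - 1]
    }
  }
  B
}

#' Fit a conductivity response function
#'
#' Count-weighted least squares of the pooled time course (above its
#' pre-onset baseline, over bins with t >= 0) in an orthonormal discrete
#' Laguerre basis. The baseline is the count-weighted mean of pre-onset
#' bins (0 when there are none). When \code{alpha} is "auto" the decay
#' parameter is chosen by minimising the leave-one-out cross-validated
#' residual (PRESS) over a coarse grid on [0.5, 0.95] refined by a line
#' search (stats::optimize). Plain residual minimisation would always
#' prefer a too-small alpha, whose compressed basis interpolates the
#' earliest noisy bins and leaves the curve unconstrained over empty bins;
#' cross-validation penalises exactly that.
#'
#' Peak metrics: peak amplitude is max(fitted) - baseline; the return to
#' baseline is the first post-peak time at which the fitted curve falls to
#' 5 percent of the peak or less.
#'
#' @param tc a \linkS4class{PooledTimecourse}
#' @param order basis size (default 10)
#' @param alpha decay in (0, 1), or "auto"
#' @return a \linkS4class{ResponseFunction}
#' @export
fitResponse <- function(tc, order = 10L, alpha = "auto") {
  stopifnot(is(tc, "PooledTimecourse"))
  pre <- tc@times < 0 & tc@counts > 0L
  baseline <- if (any(pre))
    sum(tc@values[pre] * tc@counts[pre]) / sum(tc@counts[pre]) else 0

  post <- tc@times >= 0
  tPost <- tc@times[post]
  yPost <- tc@values[post] - baseline
  wPost <- as.numeric(tc@counts[post])
  use <- wPost > 0
  if (sum(use) < order)
    stop("fewer populated bins (", sum(use), ") than basis order (", order,
         "): rank deficient")

  solveFor <- function(a) {
    B <- laguerreBasis(order, a, tPost)
    sw <- sqrt(wPost[use])
    Xw <- B[use, , drop = FALSE] * sw
    fit <- stats::lm.fit(Xw, yPost[use] * sw)
    qx <- qr(Xw)
    hat <- rowSums(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]^2)
    press <- sum((fit$residuals / pmax(1 - hat, 1e-8))^2)
    list(coef = fit$coefficients, rss = sum(fit$residuals^2),
         press = press, B = B)
  }

  if (identical(alpha, "auto")) {
    # lower limit 0.5: ten basis functions must span a multi-second window;
    # smaller alpha only arises by interpolating sparse noisy early bins
    grid <- seq(0.50, 0.90, by = 0.05)
    pg <- vapply(grid, function(a) solveFor(a)$press, numeric(1))
    a0 <- grid[which.min(pg)]
    alpha <- stats::optimize(function(a) solveFor(a)$press,
                             interval = c(max(0.50, a0 - 0.05),
                                          min(0.95, a0 + 0.05)))$minimum
  } else {
    alpha <- as.numeric(alpha)
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  }
  s <- solveFor(alpha)
  fittedCurve <- as.numeric(s$B %*% s$coef) + baseline

  # peak metrics are read only where the curve is supported by data: at
  # bins with samples or directly adjacent to one. With a full jitter
  # design every bin is populated and this changes nothing; with sparse
  # schedules it stops the peak landing on an extrapolated empty stretch.
  tPop <- tPost[use]
  step <- if (length(tPost) > 1) min(diff(tPost)) else 0.1
  supported <- vapply(tPost, function(t) min(abs(t - tPop)) <= 1.5 * step,
                      logical(1))
  searchable <- fittedCurve
  searchable[!supported] <- -Inf
  pk <- which.max(searchable)
  peakAmp <- fittedCurve[pk] - baseline
  peakT <- tPost[pk]
  back <- NA_real_
  if (peakAmp > 0) {
    later <- which(seq_along(tPost) > pk &
                   (fittedCurve - baseline) <= 0.05 * peakAmp)
    if (length(later)) back <- tPost[later[1]]
  }
  new("ResponseFunction", order = as.integer(order), alpha = alpha,
      coefficients = as.numeric(s$coef), times = tPost,
      fitted = fittedCurve, baseline = baseline, peakAmplitude = peakAmp,
      peakTime = peakT, returnToBaselineTime = back)
}

#' Peak amplitude vs stimulus property by simple linear regression
#'
#' Ordinary least squares of response-function peak amplitudes on a
#' stimulus predictor (duration in seconds, or contrast level).
#'
#' @param fits list of \linkS4class{ResponseFunction} objects, or a numeric
#'   vector of peak amplitudes
#' @param predictor predictor values, one per fit (>= 3 points, not
#'   constant)
#' @return a \linkS4class{StimulusResponseFit}
#' @export
stimulusResponseRegression <- function(fits, predictor) {
  peaks <- if (is.numeric(fits)) fits
           else vapply(fits, peakAmplitude, numeric(1))
  predictor <- as.numeric(predictor)
  if (length(peaks) != length(predictor))
    stop("one predictor value per fit is required")
  if (length(peaks) < 3) stop("at least 3 points are required")
  if (stats::sd(predictor) == 0) stop("constant predictor")
  fit <- stats::lm(peaks ~ predictor)
  r2 <- summary(fit)$r.squared
  new("StimulusResponseFit", predictor = predictor, peaks = peaks,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      rSquared = min(max(r2, 0), 1))
}

#' One-way single-score intraclass correlation coefficient
#'
#' ICC(1,1) from the one-way ANOVA decomposition:
#' (MSB - MSW) / (MSB + (k - 1) * MSW), where MSB and MSW are the between-
#' and within-subject mean squares and k the repeats per subject. Used for
#' test-retest repeatability of response functions.
#'
#' @param measurements numeric matrix, subjects x repeats (complete,
#'   balanced)
#' @return ICC estimate in [-1, 1]
#' @export
iccOneway <- function(measurements) {
  m <- as.matrix(measurements)
  if (nrow(m) < 2) stop("at least 2 subjects are required")
  if (ncol(m) < 2) stop("at least 2 repeats are required")
  if (any(!is.finite(m))) stop("measurements must be complete")
  df <- data.frame(value = as.vector(m),
                   subject = factor(rep(seq_len(nrow(m)), ncol(m))))
  av <- summary(stats::aov(value ~ subject, data = df))[[1]]
  msb <- av["subject", "Mean Sq"]
  msw <- av["Residuals", "Mean Sq"]
  k <- ncol(m)
  if (msw == 0) return(1)
  (msb - msw) / (msb + (k - 1) * msw)
}
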