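## Synthetic forward model. Per compartment the clean phase is the quadratic
## phi(r) = (mu0*omega*sigma/3)*|r - r0|^2 + offset, whose analytic Laplacian
## is 2*mu0*omega*sigma -- i.e. ground truth sits exactly inside the
## parabolic-fit reconstruction's function class, separating algorithm-
## correctness tests from model-error tests.

tissueCode <- function(x) {
  if (is.character(x)) {
    if (!x %in% names(TISSUE_CODES)) stop("unknown tissue: ", x)
    TISSUE_CODES[[x]]
  } else as.integer(x)
}

primitiveMask <- function(prim, grid) {
  dm <- grid@shape
  idx <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
  switch(prim$shape,
    sphere = {
      ctr <- prim$center; r <- prim$radius
      d2 <- outer(outer((idx[[1]] - ctr[1])^2, (idx[[2]] - ctr[2])^2, "+"),
                  (idx[[3]] - ctr[3])^2, "+")
      d2 <= r^2
    },
    ellipsoid = {
      ctr <- prim$center; sa <- prim$semiaxes
      d2 <- outer(outer(((idx[[1]] - ctr[1]) / sa[1])^2,
                        ((idx[[2]] - ctr[2]) / sa[2])^2, "+"),
                  ((idx[[3]] - ctr[3]) / sa[3])^2, "+")
      d2 <= 1
    },
    slab = {
      out <- array(FALSE, dm)
      ax <- prim$axis
      sel <- idx[[ax]] >= prim$from & idx[[ax]] <= prim$to
      if (ax == 1) out[sel, , ] <- TRUE
      else if (ax == 2) out[, sel, ] <- TRUE
      else out[, , sel] <- TRUE
      out
    },
    stop("unknown primitive shape: ", prim$shape))
}

#' Construct a PhantomSpec
#'
#' @param grid a \linkS4class{VoxelGrid}
#' @param compartments list of compartment descriptions (see
#'   \linkS4class{PhantomSpec}); painted in order, later entries override
#' @param noiseStd Gaussian phase noise, rad (default 0)
#' @param wrap wrap the output phase into [0, 2*pi)?
#' @param activation empty list for a static phantom, or list(roi,
#'   amplitude, peakTime, returnTime, onsetDelay, schedule, nFrames)
#' @param phaseCenter quadratic-phase centre r0 in voxel coordinates;
#'   defaults to the grid centre. May lie outside the volume (useful so
#'   every kernel row keeps a strong linear phase term under noise)
#' @param magnitudeLevels named amplitudes per tissue
#' @param rippleAmp relative deterministic magnitude ripple (default 0.02)
#' @param smoothPhase replace the quadratic by a Gaussian bump (non-exact
#'   fit exercise; sigma truth is then the analytic bump Laplacian)
#' @param meta an \linkS4class{AcquisitionMeta}
#' @param seed integer seed for the noise stream
#' @return a \linkS4class{PhantomSpec}
#' @export
PhantomSpec <- function(grid, compartments, noiseStd = 0, wrap = FALSE,
                        activation = list(), phaseCenter = NULL,
                        magnitudeLevels = c(background = 0.05, GM = 0.9,
                                            WM = 1.0, CSF = 1.1),
                        rippleAmp = 0.02, smoothPhase = FALSE,
                        meta = AcquisitionMeta(), seed = 1L) {
  if (is.null(phaseCenter)) phaseCenter <- (grid@shape + 1) / 2
  new("PhantomSpec", grid = grid, compartments = compartments,
      noiseStd = noiseStd, wrap = wrap, activation = activation,
      phaseCenter = as.numeric(phaseCenter),
      magnitudeLevels = magnitudeLevels, rippleAmp = rippleAmp,
      smoothPhase = smoothPhase, meta = meta, seed = as.integer(seed))
}

#' Default static two-compartment phantom
#'
#' Two disjoint spheres inside a 64^3, 3 mm isotropic grid: white matter at
#' 0.42 S/m and grey matter at 0.64 S/m — the resting tissue conductivities
#' the reconstruction should recover.
#'
#' @param n grid voxels per axis (default 64)
#' @param spacingMm isotropic spacing in mm (default 3)
#' @param sigmaWM,sigmaGM compartment conductivities, S/m
#' @param noiseStd phase noise, rad
#' @param wrap wrap the phase?
#' @param seed noise seed
#' @return a \linkS4class{PhantomSpec}
#' @export
defaultStaticPhantomSpec <- function(n = 64L, spacingMm = 3,
                                     sigmaWM = 0.42, sigmaGM = 0.64,
                                     noiseStd = 0, wrap = FALSE, seed = 1L) {
  grid <- VoxelGrid(rep(n, 3), rep(spacingMm, 3))
  ctr <- (n + 1) / 2
  r <- round(n * 0.2)
  off <- round(n * 0.195)
  comps <- list(
    list(shape = "sphere", center = c(ctr - off, ctr, ctr), radius = r,
         tissue = "WM", sigma = sigmaWM),
    list(shape = "sphere", center = c(ctr + off, ctr, ctr), radius = r,
         tissue = "GM", sigma = sigmaGM))
  PhantomSpec(grid, comps, noiseStd = noiseStd, wrap = wrap, seed = seed)
}

#' Default jittered stimulus schedule
#'
#' 16 cycles of 0.5 s stimulation at contrast 0.45, one cycle per 15.5 s
#' duty period, with onsets jittered from -0.3 s to 1.2 s in 0.1 s
#' increments in a fixed semi-randomised order.
#'
#' @param nCycles number of cycles (default 16, one per jitter value)
#' @param firstOnset nominal onset of the first cycle, s
#' @param period duty-cycle period, s (0.5 s on + 15 s off)
#' @param duration event duration, s
#' @param contrast stimulus contrast
#' @return a \linkS4class{StimulusSchedule}
#' @export
defaultJitterSchedule <- function(nCycles = 16L, firstOnset = 10,
                                  period = 15.5, duration = 0.5,
                                  contrast = 0.45) {
  jit <- seq(-0.3, 1.2, by = 0.1)
  # fixed semi-randomised order, chosen so that together with the 0.1 s
  # per-cycle drift of the 15.5 s period against the 1.2 s frame clock the
  # pooled sample residues cover every 0.1 s class of the frame duration
  # (otherwise some pooled bins would stay empty)
  perm <- c(10L, 8L, 14L, 11L, 6L, 16L, 15L, 4L, 9L, 12L, 2L, 5L, 13L, 1L,
            7L, 3L)
  jit <- rep_len(jit[perm], nCycles)
  StimulusSchedule(onsets = firstOnset + period * (seq_len(nCycles) - 1),
                   durations = duration, jitters = jit,
                   contrast = contrast)
}

#' Default dynamic phantom with a stimulus-locked conductivity increase
#'
#' A white-matter ellipsoid containing an off-centre grey-matter sphere
#' (radius 14 voxels, ~11000 voxels — the scale of an atlas region)
#' whose conductivity rises by \code{amplitude} (default 0.1 S/m, the
#' visual-stimulation increase) following each stimulus, with a gamma-like
#' unit-peak response (peak 0.7 s, back to baseline ~3 s later). Acquired
#' as 1.2 s dynamics at 3.75 mm with the default 16-cycle jittered
#' schedule. The quadratic-phase centre sits outside the volume so every
#' kernel row carries a linear phase term well above the noise.
#'
#' @param amplitude activation amplitude, S/m
#' @param noiseStd phase noise per frame, rad (default 0.05)
#' @param seed noise seed
#' @param nCycles stimulus cycles (default 16)
#' @return a \linkS4class{PhantomSpec}
#' @export
defaultDynamicPhantomSpec <- function(amplitude = 0.1, noiseStd = 0.05,
                                      seed = 1L, nCycles = 16L) {
  grid <- VoxelGrid(c(64L, 64L, 45L), rep(3.75, 3))
  ctr <- (grid@shape + 1) / 2
  roi <- list(shape = "sphere", center = c(ctr[1] + 12, ctr[2], ctr[3]),
              radius = 14, tissue = "GM", sigma = 0.64)
  comps <- list(
    list(shape = "ellipsoid", center = ctr, semiaxes = c(26.5, 26.5, 18.5),
         tissue = "WM", sigma = 0.42),
    roi)
  sched <- defaultJitterSchedule(nCycles = nCycles)
  PhantomSpec(grid, comps, noiseStd = noiseStd, wrap = FALSE,
              activation = list(roi = roi, amplitude = amplitude,
                                peakTime = 0.7, returnTime = 3.7,
                                onsetDelay = 0, schedule = sched),
              phaseCenter = ctr - c(39, 36, 28),
              meta = AcquisitionMeta(dynamicDuration = 1.2),
              seed = seed)
}

#' Unit-peak gamma-like response shape
#'
#' h(t) = ((t - t0)/tp)^a * exp(a * (1 - (t - t0)/tp)) for t > t0, else 0,
#' with tp the peak time (relative to t0) and the shape a solved so that h
#' first falls to 0.05 at \code{returnTime}.
#'
#' @param t times, s
#' @param peakTime time of the unit peak after onset delay, s
#' @param returnTime time at which h has decayed to 0.05, s
#' @param onsetDelay latency t0 before the response starts, s
#' @return h(t), unit peak
#' @export
responseShape <- function(t, peakTime = 0.7, returnTime = 3.7,
                          onsetDelay = 0) {
  if (returnTime <= peakTime + onsetDelay)
    stop("returnTime must exceed onsetDelay + peakTime")
  tr <- (returnTime - onsetDelay) / peakTime
  a <- stats::uniroot(function(a) a * (log(tr) + 1 - tr) - log(0.05),
                      interval = c(0.1, 50))$root
  tau <- (t - onsetDelay) / peakTime
  h <- ifelse(tau > 0, exp(a * (log(pmax(tau, 1e-300)) + 1 - tau)), 0)
  h[!is.finite(h)] <- 0
  h
}

# Paint compartments in order; returns region id (0 background), labels and
# per-region sigma/tissue. Errors when a compartment ends up empty.
paintCompartments <- function(spec) {
  dm <- spec@grid@shape
  region <- array(0L, dm)
  for (i in seq_along(spec@compartments)) {
    m <- primitiveMask(spec@compartments[[i]], spec@grid)
    region[m] <- i
  }
  for (i in seq_along(spec@compartments)) {
    if (!any(region == i))
      stop("compartment ", i, " has no voxels (fully overlapped?)")
  }
  labels <- array(0L, dm)
  sigma <- array(0, dm)
  for (i in seq_along(spec@compartments)) {
    cp <- spec@compartments[[i]]
    labels[region == i] <- tissueCode(cp$tissue)
    sigma[region == i] <- cp$sigma
  }
  list(region = region, labels = labels, sigma = sigma)
}

# squared distance (m^2) of every voxel centre from the phase centre
radius2m <- function(spec) {
  dm <- spec@grid@shape
  sp <- spec@grid@spacing / 1000
  ctr <- spec@phaseCenter
  x2 <- ((seq_len(dm[1]) - ctr[1]) * sp[1])^2
  y2 <- ((seq_len(dm[2]) - ctr[2]) * sp[2])^2
  z2 <- ((seq_len(dm[3]) - ctr[3]) * sp[3])^2
  outer(outer(x2, y2, "+"), z2, "+")
}

# per-region additive phase offsets keeping the clean phase continuous (in
# the mean) across region boundaries where regions touch
regionOffsets <- function(region, rawPhase) {
  n <- max(region)
  offs <- numeric(n)
  if (n <= 1) return(offs)
  dm <- dim(region)
  shifts <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (i in 2:n) {
    dsum <- 0; dcnt <- 0
    for (s in shifts) {
      a <- region[1:(dm[1] - s[1]), 1:(dm[2] - s[2]), 1:(dm[3] - s[3])]
      b <- region[(1 + s[1]):dm[1], (1 + s[2]):dm[2], (1 + s[3]):dm[3]]
      pa <- rawPhase[1:(dm[1] - s[1]), 1:(dm[2] - s[2]), 1:(dm[3] - s[3])]
      pb <- rawPhase[(1 + s[1]):dm[1], (1 + s[2]):dm[2], (1 + s[3]):dm[3]]
      sel <- a == i & b > 0 & b < i
      if (any(sel)) {
        dsum <- dsum + sum((pb[sel] + offs[b[sel]]) - pa[sel])
        dcnt <- dcnt + sum(sel)
      }
      sel <- b == i & a > 0 & a < i
      if (any(sel)) {
        dsum <- dsum + sum((pa[sel] + offs[a[sel]]) - pb[sel])
        dcnt <- dcnt + sum(sel)
      }
    }
    if (dcnt > 0) offs[i] <- dsum / dcnt
  }
  offs
}

phantomMagnitude <- function(spec, labels) {
  dm <- spec@grid@shape
  lev <- spec@magnitudeLevels[match(labels, TISSUE_CODES[names(spec@magnitudeLevels)])]
  lev <- array(as.numeric(lev), dm)
  ripple <- outer(outer(seq_len(dm[1]), seq_len(dm[2]), "+"),
                  seq_len(dm[3]), "+")
  lev * (1 + spec@rippleAmp * sin(2 * pi * ripple / 7))
}

#' Generate a static phantom
#'
#' Builds clean per-compartment quadratic phase (exactly consistent with
#' sigma = Laplacian(phi) / (2 mu0 omega)), piecewise-constant magnitude
#' with a small deterministic ripple, tissue labels, optional Gaussian
#' phase noise and optional wrapping. Ground truth is retained.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @return list(phase = PhaseVolume, magnitude = MagnitudeVolume,
#'   labels = TissueLabelMap, truth = PhantomTruth)
#' @export
makeStaticPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  painted <- paintCompartments(spec)
  omega <- 2 * pi * spec@meta@larmorHz
  r2 <- radius2m(spec)

  if (spec@smoothPhase) {
    # Gaussian bump: phi = A exp(-r^2 / (2 s^2)); analytic Laplacian
    # (r^2/s^4 - 3/s^2) phi gives the consistent sigma truth
    s <- 0.25 * max(spec@grid@shape * spec@grid@spacing) / 1000
    A <- 2
    phase <- A * exp(-r2 / (2 * s^2))
    lapl <- (r2 / s^4 - 3 / s^2) * phase
    sigmaMap <- lapl / (2 * spec@meta@mu0 * omega)
    sigmaMap[painted$region == 0L] <- 0
  } else {
    cphi <- spec@meta@mu0 * omega / 3 *
      c(0, vapply(spec@compartments, `[[`, numeric(1), "sigma"))
    phase <- cphi[painted$region + 1L] * r2
    dim(phase) <- dim(r2)
    phase[painted$region == 0L] <- 0
    offs <- regionOffsets(painted$region, phase)
    phase <- phase + array(c(0, offs)[painted$region + 1L], dim(phase))
    sigmaMap <- painted$sigma
  }

  clean <- PhaseVolume(phase, grid = spec@grid, wrapped = FALSE)
  set.seed(spec@seed)
  if (spec@noiseStd > 0)
    phase <- phase + array(stats::rnorm(length(phase), 0, spec@noiseStd),
                           dim(phase))
  wrapped <- isTRUE(spec@wrap)
  if (wrapped) phase <- rebasePhase(phase)

  list(phase = PhaseVolume(phase, grid = spec@grid, wrapped = wrapped),
       magnitude = MagnitudeVolume(phantomMagnitude(spec, painted$labels),
                                   grid = spec@grid),
       labels = TissueLabelMap(painted$labels, grid = spec@grid),
       truth = new("PhantomTruth", sigmaMap = sigmaMap,
                   activationMask = array(FALSE, spec@grid@shape),
                   responseTimes = numeric(0), responseTruth = numeric(0),
                   phaseClean = clean))
}

#' Generate a dynamic phantom with stimulus-locked activation
#'
#' Per frame, conductivity inside the activation ROI is
#' sigma(t) = sigma_base + amplitude * h(t - onset) summed over cycles,
#' with h the unit-peak response shape; the phase is rebuilt from sigma(t)
#' each frame, so the reconstruction chain can be validated against the
#' injected response. Noise is drawn independently per frame from one
#' seeded stream.
#'
#' @param spec a \linkS4class{PhantomSpec} with a nonempty activation block
#' @return list(series = DynamicPhaseSeries, magnitude = MagnitudeVolume,
#'   labels = TissueLabelMap, truth = PhantomTruth,
#'   schedule = StimulusSchedule)
#' @export
makeDynamicPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  act <- spec@activation
  if (!length(act)) stop("activation must be set for a dynamic phantom")
  sched <- act$schedule
  stopifnot(is(sched, "StimulusSchedule"))
  painted <- paintCompartments(spec)
  omega <- 2 * pi * spec@meta@larmorHz
  mu0 <- spec@meta@mu0
  r2 <- radius2m(spec)
  dm <- spec@grid@shape

  cphi <- mu0 * omega / 3 *
    c(0, vapply(spec@compartments, `[[`, numeric(1), "sigma"))
  phaseBase <- cphi[painted$region + 1L] * r2
  dim(phaseBase) <- dm
  phaseBase[painted$region == 0L] <- 0
  offs <- regionOffsets(painted$region, phaseBase)
  phaseBase <- phaseBase + array(c(0, offs)[painted$region + 1L], dm)

  roiMask <- primitiveMask(act$roi, spec@grid) & painted$region > 0L
  if (!any(roiMask)) stop("activation ROI holds no in-brain voxels")
  sigmaBase <- stats::median(painted$sigma[roiMask])
  roiR2 <- r2[roiMask]
  roiOffset <- phaseBase[roiMask] - mu0 * omega * sigmaBase / 3 * roiR2

  dt <- spec@meta@dynamicDuration
  onsetsAct <- sched@onsets + sched@jitters
  nT <- if (!is.null(act$nFrames)) act$nFrames
        else ceiling((max(onsetsAct) + 10) / dt)
  if (max(onsetsAct) > nT * dt)
    stop("schedule extends beyond the series duration")
  tmid <- (seq_len(nT) - 1) * dt + dt / 2

  pt <- if (!is.null(act$peakTime)) act$peakTime else 0.7
  rt <- if (!is.null(act$returnTime)) act$returnTime else 3.7
  od <- if (!is.null(act$onsetDelay)) act$onsetDelay else 0
  hOf <- function(t) responseShape(t, peakTime = pt, returnTime = rt,
                                   onsetDelay = od)

  vals <- array(0, c(dm, nT))
  set.seed(spec@seed)
  for (k in seq_len(nT)) {
    h <- sum(hOf(tmid[k] - onsetsAct))
    sigT <- sigmaBase + act$amplitude * h
    fr <- phaseBase
    fr[roiMask] <- mu0 * omega * sigT / 3 * roiR2 + roiOffset
    if (spec@noiseStd > 0)
      fr <- fr + array(stats::rnorm(length(fr), 0, spec@noiseStd), dm)
    if (spec@wrap) fr <- rebasePhase(fr)
    vals[, , , k] <- fr
  }

  rtimes <- seq(0, rt + 2, by = 0.1)
  truth <- new("PhantomTruth", sigmaMap = painted$sigma,
               activationMask = roiMask,
               responseTimes = rtimes,
               responseTruth = act$amplitude * hOf(rtimes),
               phaseClean = PhaseVolume(phaseBase, grid = spec@grid,
                                        wrapped = FALSE))
  list(series = DynamicPhaseSeries(vals, grid = spec@grid, meta = spec@meta,
                                   wrapped = isTRUE(spec@wrap)),
       magnitude = MagnitudeVolume(phantomMagnitude(spec, painted$labels),
                                   grid = spec@grid),
       labels = TissueLabelMap(painted$labels, grid = spec@grid),
       truth = truth, schedule = sched)
}
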