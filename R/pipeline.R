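## Config-driven pipeline chaining simulate -> unwrap -> denoise -> recon ->
## respfit -> glm. Every stage is also runnable standalone through the
## exported functions; this wrapper adds validation, logging and a JSON
## provenance sidecar.

defaultRunConfig <- function() {
  list(
    seed = 1L,
    log_level = "info",
    paths = list(phase = NULL, magnitude = NULL, labels = NULL,
                 events = NULL, out_dir = "funci-out"),
    acquisition = list(larmor_hz = DEFAULT_LARMOR_HZ, dynamic_duration = 1.2,
                       dummy_scans = 0L),
    unwrap = list(bypass = FALSE),
    denoise = list(enabled = FALSE, iterations = 400L, dt = 0.18,
                   kappa = NULL, sigmoid_slope = NULL),
    # sigma_window is wide by default: the pipeline's products are time
    # series and statistics, where censoring a noisy per-dynamic estimate
    # to a narrow plausibility window would bias responses (see vignette);
    # narrow it to c(-1, 5) when making display maps
    kernel = list(max_extent = c(9L, 9L, 6L), amplitude_tol = 0.10,
                  min_corr = 0.7, min_neighbors = 6L,
                  sigma_window = c(-30, 30)),
    response = list(order = 10L, alpha = "auto", window = c(-2, 13.4),
                    baseline_frac = 0.25),
    glm = list(t_threshold = 2.2, drift = FALSE, fdr = FALSE),
    phantom = list(enabled = TRUE, amplitude = 0.1, noise_std = 0.05,
                   n_cycles = 16L))
}

#' Validate a pipeline configuration
#'
#' Merges user settings over the defaults (which carry the pipeline's
#' standard parameter values: 9 x 9 x 6 kernel, correlation 0.7, 400
#' denoising iterations at 0.18, Laguerre order 10, t threshold 2.2).
#' Unknown keys and out-of-range values are rejected with their key path.
#'
#' @param config named list of settings (possibly nested), or a YAML path
#' @return the merged, validated configuration list
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- defaultRunConfig()
  merged <- mergeChecked(def, config, path = "")
  if (merged$kernel$min_corr <= 0 || merged$kernel$min_corr >= 1)
    stop("config error at kernel.min_corr: must lie strictly in (0, 1)")
  if (merged$denoise$dt <= 0 || merged$denoise$dt > 0.25)
    stop("config error at denoise.dt: must lie in (0, 0.25]")
  if (merged$glm$t_threshold < 0)
    stop("config error at glm.t_threshold: must be >= 0")
  if (merged$response$order < 1)
    stop("config error at response.order: must be >= 1")
  merged
}

mergeChecked <- function(def, usr, path) {
  if (!length(usr)) return(def)
  bad <- setdiff(names(usr), names(def))
  if (length(bad))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  for (k in names(usr)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      def[[k]] <- mergeChecked(def[[k]], usr[[k]],
                               paste0(path, ".", k))
    } else {
      def[[k]] <- usr[[k]]
    }
  }
  def
}

logMsg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[funCI %s] ", format(Sys.time(), "%H:%M:%S")),
          sprintf(...))
}

#' Run the full functional-conductivity pipeline
#'
#' With \code{phantom.enabled} (the default) a dynamic phantom is simulated
#' and carried through reconstruction, voxel selection, jitter pooling,
#' response fitting and GLM activation mapping; otherwise the inputs named
#' under \code{paths} are read. Stage outputs (conductivity 4D NIfTI,
#' response JSON, t map, activation mask, events TSV) and a JSON provenance
#' sidecar (package version, config, seed) are written to
#' \code{paths.out_dir}.
#'
#' @param config a config list or YAML path (see \code{\link{validateConfig}})
#' @return invisibly, a list with the stage results (series, maps, response
#'   function, activation maps, paths of written artifacts)
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  set.seed(cfg$seed)
  outDir <- cfg$paths$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  meta <- AcquisitionMeta(larmorHz = cfg$acquisition$larmor_hz,
                          dynamicDuration = cfg$acquisition$dynamic_duration,
                          dummyScans = cfg$acquisition$dummy_scans)
  spec <- KernelSpec(maxExtent = cfg$kernel$max_extent,
                     amplitudeTol = cfg$kernel$amplitude_tol,
                     minCorr = cfg$kernel$min_corr,
                     minNeighbors = cfg$kernel$min_neighbors,
                     sigmaWindow = cfg$kernel$sigma_window)

  if (isTRUE(cfg$phantom$enabled)) {
    logMsg(cfg, "simulating dynamic phantom (amplitude %.3g S/m, noise %.3g rad)",
           cfg$phantom$amplitude, cfg$phantom$noise_std)
    ph <- makeDynamicPhantom(defaultDynamicPhantomSpec(
      amplitude = cfg$phantom$amplitude, noiseStd = cfg$phantom$noise_std,
      seed = cfg$seed, nCycles = cfg$phantom$n_cycles))
    series <- ph$series; magnitude <- ph$magnitude; labels <- ph$labels
    schedule <- ph$schedule
    meta <- acquisitionMeta(series)
    roi <- ph$truth@activationMask
    bypass <- TRUE
  } else {
    p <- cfg$paths
    if (is.null(p$phase) || is.null(p$magnitude) || is.null(p$labels) ||
        is.null(p$events))
      stop("paths.phase, paths.magnitude, paths.labels and paths.events ",
           "are required when phantom.enabled is FALSE")
    series <- readSeries(p$phase, meta = meta)
    magnitude <- readVolume(p$magnitude, kind = "magnitude")
    labels <- readVolume(p$labels, kind = "labels")
    schedule <- readEvents(p$events)
    roi <- labels@values > 0
    bypass <- isTRUE(cfg$unwrap$bypass)
  }
  mask <- labels@values > 0

  if (isWrapped(series) && !bypass) {
    logMsg(cfg, "unwrapping %d frames", nFrames(series))
    for (t in seq_len(nFrames(series))) {
      fr <- PhaseVolume(series@values[, , , t, drop = TRUE],
                        grid = series@grid, wrapped = TRUE)
      series@values[, , , t] <- unwrapPhase(fr, mask)@phase@values
    }
    series@wrapped <- FALSE
  }

  if (isTRUE(cfg$denoise$enabled)) {
    logMsg(cfg, "denoising (%d iterations, dt %.3g)",
           cfg$denoise$iterations, cfg$denoise$dt)
    dp <- DiffusionParams(iterations = cfg$denoise$iterations,
                          dt = cfg$denoise$dt,
                          kappa = if (is.null(cfg$denoise$kappa)) NA_real_
                                  else cfg$denoise$kappa,
                          sigmoidSlope = if (is.null(cfg$denoise$sigmoid_slope))
                                  NA_real_ else cfg$denoise$sigmoid_slope)
    for (t in seq_len(nFrames(series))) {
      fr <- PhaseVolume(series@values[, , , t, drop = TRUE],
                        grid = series@grid, wrapped = FALSE)
      series@values[, , , t] <- denoisePhase(fr, mask, dp)@values
    }
  }

  logMsg(cfg, "reconstructing %d frames", nFrames(series))
  maps <- reconSeries(series, magnitude, labels, spec, bypassUnwrap = TRUE)
  lap1 <- phaseLaplacian(PhaseVolume(series@values[, , , 1, drop = TRUE],
                                     grid = series@grid, wrapped = FALSE),
                         magnitude, labels, spec)
  diag1 <- neighborCountHistogram(lap1, labels)
  logMsg(cfg, "neighbor-count diagnostics: %.1f%% of voxels with >= 6 neighbors",
         100 * diag1$fractionAtLeast)

  logMsg(cfg, "selecting responsive voxels and pooling")
  vox <- selectResponseVoxels(maps, schedule, roi, meta,
                              baselineFrac = cfg$response$baseline_frac)
  tc <- poolJittered(maps, schedule, vox, meta,
                     window = cfg$response$window,
                     excludeFrames = attr(vox, "selectionFrames"))
  rf <- fitResponse(tc, order = cfg$response$order,
                    alpha = cfg$response$alpha)
  logMsg(cfg, "response peak %.4f S/m at %.2f s", peakAmplitude(rf),
         peakTime(rf))

  design <- buildDesign(schedule, rf, frameMidTimes(series),
                        drift = cfg$glm$drift)
  am <- fitActivationGlm(maps, design, threshold = cfg$glm$t_threshold)
  activation <- thresholdMap(am, fdr = cfg$glm$fdr)

  sigma4d <- array(NaN, c(dim(maps[[1]]@values), length(maps)))
  for (t in seq_along(maps)) sigma4d[, , , t] <- maps[[t]]@values
  sigmaSeries <- DynamicPhaseSeries(sigma4d, grid = series@grid,
                                    meta = meta, wrapped = FALSE)
  paths <- list(
    sigma = file.path(outDir, "sigma4d.nii.gz"),
    tmap = file.path(outDir, "tmap.nii.gz"),
    activation = file.path(outDir, "activation.nii.gz"),
    events = file.path(outDir, "events.tsv"),
    response = file.path(outDir, "response.json"),
    provenance = file.path(outDir, "provenance.json"))
  writeSeries(sigmaSeries, paths$sigma)
  writeVolume(PhaseVolume(am@tmap, grid = series@grid), paths$tmap)
  writeVolume(MagnitudeVolume(array(as.numeric(activation),
                                    dim(activation)), grid = series@grid),
              paths$activation)
  writeEvents(schedule, paths$events)
  jsonlite::write_json(
    list(times = rf@times, values = tc@values, counts = tc@counts,
         coefficients = rf@coefficients, alpha = rf@alpha,
         baseline = rf@baseline, peak_amplitude = peakAmplitude(rf),
         peak_time = peakTime(rf),
         return_to_baseline_time = returnToBaselineTime(rf)),
    paths$response, auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(
    list(package = "funCI",
         version = as.character(utils::packageVersion("funCI")),
         seed = cfg$seed, config = cfg,
         config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
         n_frames = nFrames(series),
         fraction_six_neighbors = diag1$fractionAtLeast),
    paths$provenance, auto_unbox = TRUE, digits = NA, na = "null")
  logMsg(cfg, "wrote artifacts to %s", outDir)
  invisible(list(series = series, maps = maps, voxels = vox,
                 timecourse = tc, response = rf, design = design,
                 activation = am, activationMask = activation,
                 diagnostics = diag1, paths = paths))
}
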