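# allowed configuration schema: section -> keys
.configSchema <- list(
  io = c("output_dir", "trajectories", "video", "frap_bleached",
         "frap_reference", "frap_background", "image", "persistence"),
  simulate = c("kind", "eta", "eta0", "tau", "temperature",
               "bead_radius_m", "n_beads", "n_frames", "dt", "seed",
               "droplet_radius_um"),
  track = c("diameter", "min_mass", "percentile_threshold", "max_disp",
            "memory", "min_length", "noise_scale"),
  rheo = c("lag_min", "lag_max", "per_decade", "span_fraction",
           "bead_radius_m", "temperature", "dimensionality", "correction"),
  frap = c("mode", "bleach_index", "n_boot", "seed"),
  quant = c("threshold_method", "threshold", "watershed", "min_size",
            "pixel_size", "pre_event_index"))

#' Read and validate a run configuration
#'
#' YAML with one section per stage (\code{io}, \code{simulate},
#' \code{track}, \code{rheo}, \code{frap}, \code{quant}).  Unknown
#' sections or keys are rejected so that typos cannot silently fall back
#' to defaults.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return Validated named list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) .configError("configuration must be a mapping")
  badSec <- setdiff(names(cfg), names(.configSchema))
  if (length(badSec))
    .configError("unknown config section(s): ",
                 paste(badSec, collapse = ", "))
  for (sec in names(cfg)) {
    badKey <- setdiff(names(cfg[[sec]]), .configSchema[[sec]])
    if (length(badKey))
      .configError("unknown key(s) in [", sec, "]: ",
                   paste(badKey, collapse = ", "))
  }
  cfg
}

.configError <- function(...) {
  stop(structure(class = c("vptRheoConfigError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.cfgGet <- function(cfg, sec, key, default) {
  v <- cfg[[sec]][[key]]
  if (is.null(v)) default else v
}

#' Run the analysis pipeline
#'
#' Chains the package stages from a validated configuration:
#' \describe{
#'   \item{simulate}{Generate trajectories in the configured medium and
#'     write them as CSV + sidecar.}
#'   \item{track}{Detect and link beads in a TIFF video, filter, write
#'     trajectories.}
#'   \item{rheo}{Trajectories -> ensemble MSD -> smoothing -> GSER ->
#'     viscosity spectrum, zero-shear viscosity, crossover and Maxwell
#'     fit; writes \code{msd.csv}, \code{moduli.csv},
#'     \code{viscosity.csv} and \code{rheology.json}.}
#'   \item{frap}{Normalize and fit a FRAP trace; writes
#'     \code{frap.json}.}
#'   \item{quant}{Segment an image, object statistics and partition
#'     coefficients; writes \code{objects.csv} and \code{quant.json};
#'     with a persistence CSV also writes \code{persistence.json}.}
#'   \item{all}{simulate then rheo.}
#' }
#' Every run writes the fully resolved configuration
#' (\code{resolved_config.json}) and a structured log
#' (\code{run_log.txt}) recording the package version, seed, and the kT
#' temperature and dimensionality convention used for GSER.
#'
#' @param command One of "simulate", "track", "rheo", "frap", "quant",
#'   "all".
#' @param config Path to a YAML config or an equivalent list.
#' @return Invisibly, a list of the artifact paths written.
#' @export
runPipeline <- function(command = c("simulate", "track", "rheo", "frap",
                                    "quant", "all"),
                        config = list()) {
  command <- match.arg(command)
  cfg <- readRunConfig(config)
  outDir <- .cfgGet(cfg, "io", "output_dir", ".")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- c(sprintf("vptRheo %s",
                        as.character(utils::packageVersion("vptRheo"))),
                sprintf("command: %s", command))
  artifacts <- character(0)
  put <- function(...) file.path(outDir, paste0(...))

  doSimulate <- function() {
    kind <- .cfgGet(cfg, "simulate", "kind", "maxwell")
    model <- mediumModel(
      kind,
      eta = .cfgGet(cfg, "simulate", "eta", NA_real_),
      eta0 = .cfgGet(cfg, "simulate", "eta0", NA_real_),
      tau = .cfgGet(cfg, "simulate", "tau", NA_real_),
      temperature = .cfgGet(cfg, "simulate", "temperature", 303.15),
      beadRadius = .cfgGet(cfg, "simulate", "bead_radius_m", 50e-9))
    seed <- .cfgGet(cfg, "simulate", "seed", 1)
    traj <- simulateTrajectories(
      model,
      nBeads = .cfgGet(cfg, "simulate", "n_beads", 300),
      nFrames = .cfgGet(cfg, "simulate", "n_frames", 10000),
      dt = .cfgGet(cfg, "simulate", "dt", 0.015),
      seed = seed,
      dropletRadius = .cfgGet(cfg, "simulate", "droplet_radius_um", NULL))
    p <- put("trajectories.csv")
    writeTrajectories(traj, p)
    logLines <<- c(logLines, sprintf("simulate: %s seed %s -> %s",
                                     kind, seed, p))
    artifacts <<- c(artifacts, p)
    traj
  }

  doTrack <- function() {
    vp <- .cfgGet(cfg, "io", "video", NULL)
    if (is.null(vp) || !file.exists(vp))
      .configError("track: missing input video (io.video)")
    stack <- readImageStack(vp)
    ft <- locateFeatures(
      stack,
      diameter = .cfgGet(cfg, "track", "diameter", 7),
      minMass = .cfgGet(cfg, "track", "min_mass", 0),
      percentileThreshold = .cfgGet(cfg, "track", "percentile_threshold",
                                    0.9),
      noiseScale = .cfgGet(cfg, "track", "noise_scale", 1))
    traj <- linkFeatures(
      ft,
      maxDisp = .cfgGet(cfg, "track", "max_disp", 5),
      memory = .cfgGet(cfg, "track", "memory", 3),
      dt = stack@dt, pixelSize = stack@pixelSize)
    traj <- filterTrajectories(
      traj, minLength = .cfgGet(cfg, "track", "min_length", 100))
    p <- put("trajectories.csv")
    writeTrajectories(traj, p)
    logLines <<- c(logLines,
                   sprintf("track: %d trajectories -> %s",
                           nTrajectories(traj), p))
    artifacts <<- c(artifacts, p)
    traj
  }

  doRheo <- function(traj = NULL) {
    if (is.null(traj)) {
      tp <- .cfgGet(cfg, "io", "trajectories", NULL)
      if (is.null(tp) || !file.exists(tp))
        .configError("rheo: missing input trajectories (io.trajectories)")
      traj <- readTrajectories(tp)
    }
    a <- .cfgGet(cfg, "rheo", "bead_radius_m", traj@beadRadius)
    Tk <- .cfgGet(cfg, "rheo", "temperature", traj@temperature)
    dim2 <- .cfgGet(cfg, "rheo", "dimensionality", 2)
    grid <- defaultLagGrid(.cfgGet(cfg, "rheo", "lag_min", 0.015),
                           .cfgGet(cfg, "rheo", "lag_max", 100),
                           .cfgGet(cfg, "rheo", "per_decade", 20))
    msd <- smoothMSD(ensembleMSD(traj, grid),
                     .cfgGet(cfg, "rheo", "span_fraction", 0.08))
    mod <- gserModuli(msd, beadRadius = a, temperature = Tk,
                      dimensionality = dim2,
                      correction = .cfgGet(cfg, "rheo", "correction", TRUE))
    fit <- fitMaxwell(mod)
    spec <- zeroShearViscosity(viscositySpectrum(mod), fit = fit)
    cross <- crossoverTime(mod, fit = fit)
    utils::write.csv(data.frame(lag_s = msdLags(msd), msd_um2 =
                                  msdValues(msd), n_obs = msdCounts(msd)),
                     put("msd.csv"), row.names = FALSE)
    utils::write.csv(data.frame(omega_rad_s = omegas(mod),
                                Gp_Pa = elasticModulus(mod),
                                Gpp_Pa = viscousModulus(mod),
                                alpha = localSlope(mod),
                                measured = isMeasured(mod)),
                     put("moduli.csv"), row.names = FALSE)
    utils::write.csv(data.frame(omega_rad_s = omegas(spec),
                                eta_Pa_s = spec@eta),
                     put("viscosity.csv"), row.names = FALSE)
    summary <- list(
      eta0 = etaZero(spec),
      eta0_from_fit = spec@fromFit,
      plateau_omega_lo = plateauRange(spec)[1],
      plateau_omega_hi = plateauRange(spec)[2],
      tau_rel = cross$tauRel,
      omega_c = cross$omegaC,
      crossover_extrapolated = cross$extrapolated,
      G0 = plateauModulus(fit),
      tau_fit = relaxationTime(fit),
      eta0_fit = etaZero(fit),
      fit_residual = fit@residual,
      bead_radius_m = a, temperature_K = Tk, dimensionality = dim2)
    jsonlite::write_json(summary, put("rheology.json"), auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    logLines <<- c(logLines,
                   sprintf("rheo: kT at T = %g K, %gD MSD converted x%g",
                           Tk, dim2, 3 / dim2),
                   sprintf("rheo: eta0 = %g Pa s, tau_rel = %g s",
                           etaZero(spec), cross$tauRel))
    artifacts <<- c(artifacts, put("msd.csv"), put("moduli.csv"),
                    put("viscosity.csv"), put("rheology.json"))
  }

  doFrap <- function() {
    bp <- .cfgGet(cfg, "io", "frap_bleached", NULL)
    if (is.null(bp) || !file.exists(bp))
      .configError("frap: missing input trace (io.frap_bleached)")
    bleached <- readIntensityTrace(bp, role = "bleached")
    refPath <- .cfgGet(cfg, "io", "frap_reference", NULL)
    bgPath <- .cfgGet(cfg, "io", "frap_background", NULL)
    reference <- if (!is.null(refPath))
      readIntensityTrace(refPath, role = "reference") else NULL
    background <- if (!is.null(bgPath))
      readIntensityTrace(bgPath, role = "background") else NULL
    norm <- normalizeFrap(bleached, reference, background,
                          mode = .cfgGet(cfg, "frap", "mode",
                                         "in_vitro_reference"),
                          bleachIndex = .cfgGet(cfg, "frap",
                                                "bleach_index", NULL))
    fit <- fitOnePhase(norm,
                       nBoot = .cfgGet(cfg, "frap", "n_boot", 500),
                       seed = .cfgGet(cfg, "frap", "seed", 1))
    out <- list(plateau = fit@plateau, k = fit@k,
                half_time_s = fit@halfTime,
                final_value = fit@finalValue,
                plateau_ci = fit@ci[1, ], k_ci = fit@ci[2, ],
                flags = fit@flags)
    jsonlite::write_json(out, put("frap.json"), auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    logLines <<- c(logLines, sprintf("frap: plateau %.3f k %.4g",
                                     fit@plateau, fit@k))
    artifacts <<- c(artifacts, put("frap.json"))
  }

  doQuant <- function() {
    ip <- .cfgGet(cfg, "io", "image", NULL)
    out <- list()
    if (!is.null(ip)) {
      if (!file.exists(ip)) .configError("quant: image not found: ", ip)
      stack <- readImageStack(ip)
      img <- stack@pixels[, , 1]
      ps <- .cfgGet(cfg, "quant", "pixel_size",
                    if (is.finite(stack@pixelSize)) stack@pixelSize else 1)
      labels <- segmentCondensates(
        img,
        thresholdMethod = .cfgGet(cfg, "quant", "threshold_method", "otsu"),
        threshold = .cfgGet(cfg, "quant", "threshold", NULL),
        watershed = .cfgGet(cfg, "quant", "watershed", FALSE),
        minSize = .cfgGet(cfg, "quant", "min_size", 9))
      st <- objectStats(img, labels, pixelSize = ps)
      pc <- if (max(labels) > 0) partitionCoefficient(img, labels) else NULL
      utils::write.csv(st$objects, put("objects.csv"), row.names = FALSE)
      out <- c(out, st$summary,
               list(mean_partition_ratio =
                      if (is.null(pc)) NA else pc$summary$mean_ratio))
      artifacts <<- c(artifacts, put("objects.csv"))
    }
    pp <- .cfgGet(cfg, "io", "persistence", NULL)
    if (!is.null(pp)) {
      if (!file.exists(pp)) .configError("quant: persistence not found: ", pp)
      d <- utils::read.csv(pp)
      if (!all(c("t_s", "value") %in% names(d)))
        .configError("persistence CSV needs columns t_s and value")
      pcv <- persistenceCurve(d$t_s, d$value,
                              .cfgGet(cfg, "quant", "pre_event_index", 1))
      out$fraction_remaining <- as.list(pcv@fractionRemaining)
      out$half_time_s <- pcv@halfTime
    }
    if (!length(out)) .configError("quant: no inputs configured")
    jsonlite::write_json(out, put("quant.json"), auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    artifacts <<- c(artifacts, put("quant.json"))
  }

  switch(command,
         simulate = doSimulate(),
         track = doTrack(),
         rheo = doRheo(),
         frap = doFrap(),
         quant = doQuant(),
         all = doRheo(doSimulate()))

  jsonlite::write_json(cfg, file.path(outDir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  writeLines(logLines, file.path(outDir, "run_log.txt"))
  invisible(c(artifacts, file.path(outDir, "resolved_config.json")))
}
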