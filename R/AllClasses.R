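# Boltzmann constant, J/K
.kB <- 1.380649e-23

#' MediumModel: a viscoelastic medium for generative oracles and simulation
#'
#' Describes the medium surrounding a tracer bead, either a Newtonian fluid
#' of viscosity \code{eta} or a single-relaxation-time Maxwell fluid with
#' zero-shear viscosity \code{eta0} and relaxation time \code{tau} (implied
#' plateau modulus \eqn{G_0 = \eta_0/\tau}).  The temperature and bead
#' radius ride along because every Stokes-Einstein quantity needs them.
#'
#' @slot kind "newtonian" or "maxwell".
#' @slot eta Newtonian viscosity, Pa s (NA for maxwell).
#' @slot eta0 Zero-shear viscosity, Pa s (NA for newtonian).
#' @slot tau Terminal relaxation time, s (NA for newtonian).
#' @slot temperature Absolute temperature, K.
#' @slot beadRadius Tracer bead radius, m.
#' @exportClass MediumModel
setClass("MediumModel",
  representation(kind = "character", eta = "numeric", eta0 = "numeric",
                 tau = "numeric", temperature = "numeric",
                 beadRadius = "numeric"))

setValidity("MediumModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("newtonian", "maxwell"))
    msg <- c(msg, "kind must be 'newtonian' or 'maxwell'")
  if (!is.finite(object@temperature) || object@temperature <= 0)
    msg <- c(msg, "temperature must be positive")
  if (!is.finite(object@beadRadius) || object@beadRadius <= 0)
    msg <- c(msg, "beadRadius must be positive")
  if (identical(object@kind, "newtonian")) {
    if (!is.finite(object@eta) || object@eta <= 0)
      msg <- c(msg, "newtonian model needs eta > 0")
  } else if (identical(object@kind, "maxwell")) {
    if (!is.finite(object@eta0) || object@eta0 <= 0)
      msg <- c(msg, "maxwell model needs eta0 > 0")
    if (!is.finite(object@tau) || object@tau <= 0)
      msg <- c(msg, "maxwell model needs tau > 0")
    if (is.finite(object@eta0) && is.finite(object@tau) &&
        !is.finite(object@eta0 / object@tau))
      msg <- c(msg, "implied plateau modulus eta0/tau must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' TrajectorySet: time-stamped 2D bead positions with acquisition metadata
#'
#' @slot data data.frame with columns \code{trajectory_id}, \code{frame},
#'   \code{t_s}, \code{x_um}, \code{y_um}.
#' @slot dt Frame interval, s.
#' @slot pixelSize Pixel size, um/px (NA when positions were generated
#'   directly in um).
#' @slot beadRadius Bead radius, m.
#' @slot temperature Temperature, K.
#' @slot seed Seed used by the generator (NA for tracked data).
#' @exportClass TrajectorySet
setClass("TrajectorySet",
  representation(data = "data.frame", dt = "numeric", pixelSize = "numeric",
                 beadRadius = "numeric", temperature = "numeric",
                 seed = "numeric"))

setValidity("TrajectorySet", function(object) {
  d <- object@data
  need <- c("trajectory_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(d)))
    return(paste("data must have columns", paste(need, collapse = ", ")))
  if (!is.finite(object@dt) || object@dt <= 0)
    return("dt must be positive")
  if (nrow(d) > 1) {
    ord <- order(d$trajectory_id, d$frame)
    dd <- d[ord, ]
    same <- dd$trajectory_id[-1] == dd$trajectory_id[-nrow(dd)]
    if (any(same & diff(dd$frame) <= 0))
      return("frames must be strictly increasing within a trajectory")
  }
  TRUE
})

#' MSDCurve: ensemble mean squared displacement versus lag time
#'
#' @slot lags Lag times, s, strictly increasing.
#' @slot msd Mean squared displacement, um^2.
#' @slot nObs Displacement-pair count entering each lag.
#' @slot dimensionality Spatial dimensionality of the displacement (2 for
#'   in-plane video tracking).
#' @slot beadRadius Bead radius, m.
#' @slot temperature Temperature, K.
#' @slot dt Frame interval of the source data, s (NA for analytic curves).
#' @slot smoothed Whether a moving average has been applied.
#' @exportClass MSDCurve
setClass("MSDCurve",
  representation(lags = "numeric", msd = "numeric", nObs = "numeric",
                 dimensionality = "numeric", beadRadius = "numeric",
                 temperature = "numeric", dt = "numeric",
                 smoothed = "logical"))

setValidity("MSDCurve", function(object) {
  msg <- character()
  n <- length(object@lags)
  if (length(object@msd) != n || length(object@nObs) != n)
    msg <- c(msg, "lags, msd and nObs must have equal length")
  if (n > 1 && any(diff(object@lags) <= 0))
    msg <- c(msg, "lags must be strictly increasing")
  if (any(object@msd < 0, na.rm = TRUE))
    msg <- c(msg, "msd must be non-negative")
  if (any(object@lags == 0 & object@msd != 0))
    msg <- c(msg, "msd at zero lag must be zero")
  if (length(msg)) msg else TRUE
})

#' ModuliCurves: elastic and viscous moduli versus angular frequency
#'
#' @slot omega Angular frequency, rad/s, strictly increasing.
#' @slot Gp Elastic (storage) modulus G', Pa.
#' @slot Gpp Viscous (loss) modulus G'', Pa.
#' @slot alpha Local log-log slope of the MSD at t = 1/omega, clamped to
#'   the physical band [0, 1].
#' @slot measured TRUE for points derived from measured MSD, FALSE for
#'   points extrapolated from a model fit.
#' @slot beadRadius Bead radius, m.
#' @slot temperature Temperature, K.
#' @slot omegaC First G'-G'' crossover frequency, rad/s (NA when unknown).
#' @exportClass ModuliCurves
setClass("ModuliCurves",
  representation(omega = "numeric", Gp = "numeric", Gpp = "numeric",
                 alpha = "numeric", measured = "logical",
                 beadRadius = "numeric", temperature = "numeric",
                 omegaC = "numeric"))

setValidity("ModuliCurves", function(object) {
  msg <- character()
  n <- length(object@omega)
  if (length(object@Gp) != n || length(object@Gpp) != n ||
      length(object@alpha) != n || length(object@measured) != n)
    msg <- c(msg, "omega, Gp, Gpp, alpha, measured must have equal length")
  if (n > 1 && any(diff(object@omega) <= 0))
    msg <- c(msg, "omega must be strictly increasing")
  if (any(object@alpha < 0 | object@alpha > 1, na.rm = TRUE))
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (any(object@Gp < 0, na.rm = TRUE) || any(object@Gpp < 0, na.rm = TRUE))
    msg <- c(msg, "moduli must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ViscositySpectrum: frequency-dependent viscosity eta(omega) = G''/omega
#'
#' @slot omega Angular frequency, rad/s.
#' @slot eta Viscosity, Pa s.
#' @slot plateauRange Low/high omega bounding the detected low-frequency
#'   plateau (NA before plateau detection).
#' @slot eta0 Zero-shear viscosity from the plateau mean (NA before
#'   detection).
#' @slot fromFit TRUE when eta0 fell back to a Maxwell-fit value because no
#'   plateau was found in the measured band.
#' @exportClass ViscositySpectrum
setClass("ViscositySpectrum",
  representation(omega = "numeric", eta = "numeric",
                 plateauRange = "numeric", eta0 = "numeric",
                 fromFit = "logical"))

setValidity("ViscositySpectrum", function(object) {
  if (length(object@eta) != length(object@omega))
    return("omega and eta must have equal length")
  if (any(object@eta < 0, na.rm = TRUE)) return("eta must be non-negative")
  TRUE
})

#' MaxwellFit: a single-relaxation-time Maxwell fluid fitted to moduli
#'
#' @slot G0 Plateau modulus, Pa.
#' @slot tau Relaxation time, s.
#' @slot eta0 Zero-shear viscosity G0*tau, Pa s.
#' @slot omegaC Crossover frequency 1/tau, rad/s.
#' @slot residual Root-mean-square log10 residual of the joint fit.
#' @slot converged Whether the optimiser converged.
#' @slot flags Character flags, e.g. "model_mismatch".
#' @exportClass MaxwellFit
setClass("MaxwellFit",
  representation(G0 = "numeric", tau = "numeric", eta0 = "numeric",
                 omegaC = "numeric", residual = "numeric",
                 converged = "logical", flags = "character"))

setValidity("MaxwellFit", function(object) {
  msg <- character()
  if (!is.finite(object@G0) || object@G0 <= 0) msg <- c(msg, "G0 must be > 0")
  if (!is.finite(object@tau) || object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (is.finite(object@G0) && is.finite(object@tau)) {
    if (abs(object@eta0 - object@G0 * object@tau) >
        1e-8 * max(1, object@eta0))
      msg <- c(msg, "eta0 must equal G0*tau")
    if (abs(object@omegaC * object@tau - 1) > 1e-8)
      msg <- c(msg, "omegaC must equal 1/tau")
  }
  if (length(msg)) msg else TRUE
})

#' IntensityTrace: fluorescence intensity versus time
#'
#' Used for FRAP recovery, dilution-retention and extrusion-persistence
#' readouts.  Normalized traces may stray slightly outside [0, 1] from
#' noise; validity allows [-0.2, 1.2].
#'
#' @slot t Time, s, strictly increasing.
#' @slot value Intensity (arbitrary units, or unitless when normalized).
#' @slot role One of "bleached", "reference", "background", "normalized".
#' @slot bleachIndex Index of the first post-bleach time point (NA when not
#'   applicable).
#' @exportClass IntensityTrace
setClass("IntensityTrace",
  representation(t = "numeric", value = "numeric", role = "character",
                 bleachIndex = "numeric"))

setValidity("IntensityTrace", function(object) {
  msg <- character()
  if (length(object@t) != length(object@value))
    msg <- c(msg, "t and value must have equal length")
  if (length(object@t) > 1 && any(diff(object@t) <= 0))
    msg <- c(msg, "t must be strictly increasing")
  if (!object@role %in% c("bleached", "reference", "background", "normalized"))
    msg <- c(msg, "unknown role")
  if (identical(object@role, "normalized") &&
      any(object@value < -0.2 | object@value > 1.2, na.rm = TRUE))
    msg <- c(msg, "normalized values must lie in [-0.2, 1.2]")
  if (length(msg)) msg else TRUE
})

#' FRAPFit: one-phase exponential recovery fit
#'
#' Model: I(t) = plateau * (1 - exp(-k t)) with I(0) fixed at 0, the floor
#' enforced by the normalization conventions.
#'
#' @slot plateau Mobile fraction (recovery plateau), unitless.
#' @slot k Recovery rate, 1/s.
#' @slot halfTime ln(2)/k, s.
#' @slot ci 2x2 matrix of bootstrap 95\% confidence bounds (rows plateau,
#'   k; columns lower, upper).
#' @slot finalValue Mean of the last time point, the descriptive
#'   "recovery at end of observation" summary.
#' @slot flags Character flags, e.g. "k_unidentifiable", "ci_unreliable".
#' @exportClass FRAPFit
setClass("FRAPFit",
  representation(plateau = "numeric", k = "numeric", halfTime = "numeric",
                 ci = "matrix", finalValue = "numeric", flags = "character"))

setValidity("FRAPFit", function(object) {
  msg <- character()
  if (!is.finite(object@plateau) || object@plateau < 0 ||
      object@plateau > 1.2)
    msg <- c(msg, "plateau must lie in [0, 1.2]")
  if (!is.finite(object@k) || object@k <= 0)
    msg <- c(msg, "k must be positive")
  if (is.finite(object@k) &&
      abs(object@halfTime - log(2) / object@k) > 1e-8 * object@halfTime)
    msg <- c(msg, "halfTime must equal ln(2)/k")
  if (length(msg)) msg else TRUE
})

#' ImageStack: a stack of fluorescence frames with acquisition metadata
#'
#' @slot pixels Numeric array, row x col x frame.
#' @slot dt Frame interval, s.
#' @slot pixelSize Pixel size, um/px.
#' @exportClass ImageStack
setClass("ImageStack",
  representation(pixels = "array", dt = "numeric", pixelSize = "numeric"))

setValidity("ImageStack", function(object) {
  if (length(dim(object@pixels)) != 3) return("pixels must be 3D")
  if (dim(object@pixels)[3] < 1) return("need at least one frame")
  if (!is.finite(object@dt) || object@dt <= 0) return("dt must be positive")
  TRUE
})

#' PersistenceCurve: normalized integrated density versus time
#'
#' @slot t Time, s.
#' @slot raw Raw integrated density, a.u.
#' @slot normalized Trace divided by the pre-event value.
#' @slot fractionRemaining Named numeric: normalized value at requested
#'   horizons (names are times in s).
#' @slot halfTime First time the normalized trace crosses 0.5 (NA when
#'   never crossed).
#' @exportClass PersistenceCurve
setClass("PersistenceCurve",
  representation(t = "numeric", raw = "numeric", normalized = "numeric",
                 fractionRemaining = "numeric", halfTime = "numeric"))

setValidity("PersistenceCurve", function(object) {
  if (length(object@t) != length(object@raw) ||
      length(object@t) != length(object@normalized))
    return("t, raw and normalized must have equal length")
  TRUE
})
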