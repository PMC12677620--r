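#' Construct a viscoelastic medium model
#'
#' The generative description of the medium a tracer bead sits in.  A
#' Newtonian medium is a plain viscous fluid; a Maxwell medium is the
#' single-relaxation-time viscoelastic fluid with creep compliance
#' \deqn{J(t) = 1/G_0 + t/\eta_0, \qquad G_0 = \eta_0/\tau,}
#' i.e. an elastic cage that relaxes on time scale \code{tau} on top of
#' terminal flow with zero-shear viscosity \code{eta0}.
#'
#' Defaults reflect typical condensate microrheology acquisition: 100 nm
#' diameter tracer beads (radius 50 nm) imaged at 30 C (303.15 K).
#'
#' @param kind "maxwell" or "newtonian".
#' @param eta Newtonian viscosity, Pa s.
#' @param eta0 Maxwell zero-shear viscosity, Pa s.
#' @param tau Maxwell terminal relaxation time, s.
#' @param temperature Absolute temperature for kT, K.
#' @param beadRadius Tracer bead radius, m.
#' @return A \linkS4class{MediumModel}.
#' @examples
#' m <- mediumModel("maxwell", eta0 = 31.8, tau = 4.6)
#' plateauModulus(m)
#' @export
mediumModel <- function(kind = c("maxwell", "newtonian"), eta = NA_real_,
                        eta0 = NA_real_, tau = NA_real_,
                        temperature = 303.15, beadRadius = 50e-9) {
  kind <- match.arg(kind)
  methods::new("MediumModel", kind = kind, eta = as.numeric(eta),
               eta0 = as.numeric(eta0), tau = as.numeric(tau),
               temperature = as.numeric(temperature),
               beadRadius = as.numeric(beadRadius))
}

#' @rdname vptRheo-accessors
setMethod("modelKind", "MediumModel", function(x) x@kind)
#' @rdname vptRheo-accessors
setMethod("beadRadius", "MediumModel", function(x) x@beadRadius)
#' @rdname vptRheo-accessors
setMethod("temperature", "MediumModel", function(x) x@temperature)

#' @rdname vptRheo-accessors
setMethod("plateauModulus", "MediumModel", function(x) {
  if (x@kind == "maxwell") x@eta0 / x@tau else NA_real_
})

#' @rdname vptRheo-accessors
setMethod("relaxationTime", "MediumModel", function(x) {
  if (x@kind == "maxwell") x@tau else NA_real_
})

#' @rdname vptRheo-accessors
setMethod("etaZero", "MediumModel", function(x) {
  if (x@kind == "maxwell") x@eta0 else x@eta
})

#' @rdname vptRheo-accessors
setMethod("diffusionCoefficient", "MediumModel", function(x) {
  # terminal Stokes-Einstein diffusivity, m^2/s
  .kB * x@temperature / (6 * pi * etaZero(x) * x@beadRadius)
})

setMethod("show", "MediumModel", function(object) {
  if (object@kind == "newtonian") {
    cat(sprintf("MediumModel: newtonian, eta = %g Pa s\n", object@eta))
  } else {
    cat(sprintf(
      "MediumModel: maxwell, eta0 = %g Pa s, tau = %g s (G0 = %g Pa)\n",
      object@eta0, object@tau, plateauModulus(object)))
  }
  cat(sprintf("  T = %g K, bead radius = %g nm, D = %.4g um^2/s\n",
              object@temperature, object@beadRadius * 1e9,
              diffusionCoefficient(object) * 1e12))
})

#' Closed-form mean squared displacement of a bead in the medium
#'
#' The exact 2D ensemble MSD implied by the generalized Stokes-Einstein
#' relation for the medium's creep compliance:
#' \deqn{\langle\Delta r^2(t)\rangle_{2D} = \frac{2}{3}\,
#'   \frac{k_B T}{\pi a}\, J(t)}
#' with \eqn{J(t) = t/\eta} (Newtonian) or \eqn{J(t) = 1/G_0 + t/\eta_0}
#' (Maxwell).  Serves as the generative oracle for the simulator and the
#' inversion chain.
#'
#' @param model A \linkS4class{MediumModel}.
#' @param lags Lag times, s, sorted ascending, \code{>= 0}.  A zero lag
#'   maps to zero displacement.
#' @return An \linkS4class{MSDCurve} (um^2, dimensionality 2).
#' @examples
#' m <- mediumModel("newtonian", eta = 1e-3)
#' msdValues(analyticMSD(m, 1))  # 4 D, with D = kT/(6 pi eta a)
#' @export
analyticMSD <- function(model, lags) {
  stopifnot(is(model, "MediumModel"))
  methods::validObject(model)
  if (any(lags < 0)) stop("lags must be >= 0")
  if (is.unsorted(lags, strictly = TRUE)) stop("lags must be sorted ascending")
  kT <- .kB * model@temperature
  a <- model@beadRadius
  J <- if (model@kind == "newtonian") {
    lags / model@eta
  } else {
    1 / plateauModulus(model) + lags / model@eta0
  }
  msd <- (2 / 3) * (kT / (pi * a)) * J * 1e12   # m^2 -> um^2
  msd[lags == 0] <- 0
  methods::new("MSDCurve", lags = as.numeric(lags), msd = msd,
               nObs = rep(Inf, length(lags)), dimensionality = 2,
               beadRadius = a, temperature = model@temperature,
               dt = NA_real_, smoothed = TRUE)
}

#' Closed-form viscoelastic moduli of the medium
#'
#' Maxwell: \eqn{G'(\omega) = G_0\omega^2\tau^2/(1+\omega^2\tau^2)},
#' \eqn{G''(\omega) = G_0\omega\tau/(1+\omega^2\tau^2)}; the moduli cross
#' at \eqn{\omega_c = 1/\tau} where both equal \eqn{G_0/2}.
#' Newtonian: \eqn{G' = 0}, \eqn{G'' = \eta\omega}.
#'
#' @param model A \linkS4class{MediumModel}.
#' @param omegas Angular frequencies, rad/s, \code{> 0}, sorted ascending.
#' @return A \linkS4class{ModuliCurves}; for Maxwell media the crossover
#'   \code{omegaC = 1/tau} is recorded.
#' @export
analyticModuli <- function(model, omegas) {
  stopifnot(is(model, "MediumModel"))
  methods::validObject(model)
  if (any(omegas <= 0)) stop("omegas must be > 0")
  if (is.unsorted(omegas, strictly = TRUE))
    stop("omegas must be sorted ascending")
  omegas <- as.numeric(omegas)
  if (model@kind == "newtonian") {
    Gp <- rep(0, length(omegas))
    Gpp <- model@eta * omegas
    alpha <- rep(1, length(omegas))
    wc <- NA_real_
  } else {
    G0 <- plateauModulus(model)
    wt2 <- (omegas * model@tau)^2
    Gp <- G0 * wt2 / (1 + wt2)
    Gpp <- G0 * omegas * model@tau / (1 + wt2)
    # d ln MSD / d ln t evaluated at t = 1/omega
    alpha <- 1 / (1 + omegas * model@tau)
    wc <- 1 / model@tau
  }
  methods::new("ModuliCurves", omega = omegas, Gp = Gp, Gpp = Gpp,
               alpha = alpha, measured = rep(TRUE, length(omegas)),
               beadRadius = model@beadRadius,
               temperature = model@temperature, omegaC = wc)
}
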