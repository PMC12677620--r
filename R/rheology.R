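#' Default log-spaced lag grid
#'
#' 20 points per decade between \code{from} and \code{to}; the default
#' span 0.015-100 s covers a 15 ms frame interval out to the longest lag
#' used for the moduli.
#'
#' @param from,to Lag range, s.
#' @param perDecade Grid density.
#' @return Numeric vector of lags, s.
#' @export
defaultLagGrid <- function(from = 0.015, to = 100, perDecade = 20) {
  n <- max(2, ceiling(log10(to / from) * perDecade) + 1)
  exp(seq(log(from), log(to), length.out = n))
}

#' Ensemble mean squared displacement
#'
#' Per-trajectory time-averaged MSD over all overlapping displacement
#' pairs at each lag, ensemble-averaged with pair-count weighting (the
#' grand mean over every pair).  Lags are snapped to integer multiples of
#' the frame interval; lags exceeding every trajectory span are dropped
#' with a warning.  Trajectories with frame gaps (from linking memory)
#' contribute only the pairs both of whose endpoints were observed.
#'
#' @param traj A \linkS4class{TrajectorySet}.
#' @param lagGrid Lag times, s; default \code{\link{defaultLagGrid}()}.
#' @return An \linkS4class{MSDCurve} (2D, um^2) carrying the trajectory
#'   metadata.
#' @export
ensembleMSD <- function(traj, lagGrid = defaultLagGrid()) {
  stopifnot(is(traj, "TrajectorySet"))
  d <- traj@data
  if (!nrow(d)) stop("need at least one trajectory")
  dt <- traj@dt
  lagFrames <- sort(unique(pmax(1L, as.integer(round(lagGrid / dt)))))
  ids <- unique(d$trajectory_id)
  # per-trajectory position vectors indexed by frame (NA at gaps)
  ss <- numeric(length(lagFrames))
  np <- numeric(length(lagFrames))
  byId <- split(seq_len(nrow(d)), d$trajectory_id)
  for (idx in byId) {
    fr <- d$frame[idx]
    o <- order(fr); fr <- fr[o]
    x <- d$x_um[idx][o]; y <- d$y_um[idx][o]
    span <- fr[length(fr)] - fr[1]
    rel <- fr - fr[1] + 1L
    gx <- rep(NA_real_, span + 1L); gy <- gx
    gx[rel] <- x; gy[rel] <- y
    for (i in seq_along(lagFrames)) {
      n <- lagFrames[i]
      if (n > span) break
      dx <- gx[(n + 1):(span + 1)] - gx[1:(span + 1 - n)]
      dy <- gy[(n + 1):(span + 1)] - gy[1:(span + 1 - n)]
      sq <- dx * dx + dy * dy
      ok <- !is.na(sq)
      ss[i] <- ss[i] + sum(sq[ok])
      np[i] <- np[i] + sum(ok)
    }
  }
  keep <- np > 0
  if (!all(keep))
    warning(sum(!keep), " lag(s) exceed every trajectory span; dropped")
  if (!any(keep)) stop("no lag is covered by any trajectory")
  methods::new("MSDCurve", lags = lagFrames[keep] * dt,
               msd = ss[keep] / np[keep], nObs = np[keep],
               dimensionality = 2, beadRadius = traj@beadRadius,
               temperature = traj@temperature, dt = dt, smoothed = FALSE)
}

#' @rdname vptRheo-accessors
setMethod("msdLags", "MSDCurve", function(x) x@lags)
#' @rdname vptRheo-accessors
setMethod("msdValues", "MSDCurve", function(x) x@msd)
#' @rdname vptRheo-accessors
setMethod("msdCounts", "MSDCurve", function(x) x@nObs)
#' @rdname vptRheo-accessors
setMethod("beadRadius", "MSDCurve", function(x) x@beadRadius)
#' @rdname vptRheo-accessors
setMethod("temperature", "MSDCurve", function(x) x@temperature)

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf(
    "MSDCurve: %d lags %.3g..%.3g s, %dD%s\n", length(object@lags),
    min(object@lags), max(object@lags), as.integer(object@dimensionality),
    if (isTRUE(object@smoothed)) ", smoothed" else ""))
})

#' Moving-average smoothing of an MSD curve
#'
#' Centred moving average in log-lag index space with a window of
#' \code{spanFraction} of the number of lag points (shrunken symmetric
#' windows at the endpoints); the lags themselves are unchanged.  Mirrors
#' the usual practice of smoothing the averaged MSD with a span below 10
#' percent of the series length, hence \code{spanFraction} must be <0.1.
#'
#' @param curve An \linkS4class{MSDCurve}.
#' @param spanFraction Window size as a fraction of the number of points,
#'   in (0, 0.1).
#' @return The smoothed \linkS4class{MSDCurve} (\code{smoothed} flag set).
#' @export
smoothMSD <- function(curve, spanFraction = 0.08) {
  stopifnot(is(curve, "MSDCurve"))
  if (spanFraction <= 0 || spanFraction >= 0.1)
    stop("spanFraction must lie in (0, 0.1)")
  n <- length(curve@lags)
  half <- floor(spanFraction * n / 2)
  if (2 * half + 1 < 3) {
    warning("smoothing span covers fewer than 3 points; returning input")
    curve@smoothed <- TRUE
    return(curve)
  }
  sm <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1, n - i)   # shrink symmetrically at endpoints
    mean(curve@msd[(i - h):(i + h)])
  }, numeric(1))
  curve@msd <- sm
  curve@smoothed <- TRUE
  curve
}

# local polynomial derivatives of y(x) at every x: returns cbind(d1, d2).
# Quadratic fit over +/- halfWindow points; tolerates non-uniform x.
.localDerivs <- function(x, y, halfWindow = 4) {
  n <- length(x)
  d1 <- numeric(n); d2 <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - halfWindow); hi <- min(n, i + halfWindow)
    idx <- lo:hi
    if (length(idx) < 3) {
      idx <- max(1, i - 1):min(n, i + 1)
    }
    xx <- x[idx] - x[i]
    deg <- min(2, length(idx) - 1)
    X <- outer(xx, 0:deg, `^`)
    cf <- stats::.lm.fit(X, y[idx])$coefficients
    d1[i] <- cf[2]
    d2[i] <- if (deg >= 2) 2 * cf[3] else 0
  }
  cbind(d1, d2)
}

#' Invert an MSD curve to viscoelastic moduli (Mason GSER)
#'
#' Mason's local power-law inversion of the generalized Stokes-Einstein
#' relation.  At each lag \eqn{t}, with \eqn{\omega = 1/t} and
#' \eqn{\alpha(\omega) = d\ln \mathrm{MSD}/d\ln t} (clamped to [0, 1]):
#' \deqn{|G^*(\omega)| = \frac{k_B T}{\pi a\,
#'   \mathrm{MSD_{3D}}(t)\, \Gamma[1 + \alpha]},\qquad
#'   G' = |G^*|\cos(\pi\alpha/2),\; G'' = |G^*|\sin(\pi\alpha/2).}
#' The tracked MSD is 2D and is converted to its 3D equivalent by the
#' factor \eqn{3/d} before the formula.
#'
#' With \code{correction = TRUE} (default) the estimate also carries the
#' second-order term of the local log-parabola model: with
#' \eqn{\beta = d^2\ln\mathrm{MSD}/d(\ln t)^2}, the complex modulus is
#' divided by
#' \deqn{C = 1 + \tfrac{\beta}{2}\left[\psi_1(1+\alpha) +
#'   \psi_0(1+\alpha)^2 - \pi^2/4 - i\pi\psi_0(1+\alpha)\right],}
#' obtained from the unilateral Fourier transform of
#' \eqn{t^{\alpha} e^{(\beta/2)\ln^2(\omega t)}}.  The correction brings
#' the estimate within a few percent of closed forms near spectral
#' transitions, where the plain power-law approximation errs by ~20%; it
#' slightly shifts the G'-G'' crossover (the uncorrected estimator
#' locates the Maxwell crossover exactly, by phase symmetry at
#' \eqn{\alpha = 1/2}).
#'
#' @param curve A smoothed, strictly positive \linkS4class{MSDCurve}.
#' @param beadRadius Bead radius, m; default from the curve metadata.
#' @param temperature Temperature for kT, K; default from the curve.
#' @param dimensionality Override the curve's displacement dimensionality
#'   (2 for in-plane tracking).
#' @param correction Apply the second-order log-curvature correction.
#' @param halfWindow Points on each side entering the local log-log
#'   polynomial fit for the derivatives.
#' @return A \linkS4class{ModuliCurves} over \eqn{\omega = 1/\mathrm{lag}}
#'   (ascending), all points flagged measured.  Points with non-finite
#'   log-derivatives are dropped with a warning.
#' @export
gserModuli <- function(curve, beadRadius = NULL, temperature = NULL,
                       dimensionality = NULL, correction = TRUE,
                       halfWindow = 4) {
  stopifnot(is(curve, "MSDCurve"))
  a <- if (is.null(beadRadius)) curve@beadRadius else beadRadius
  Tk <- if (is.null(temperature)) curve@temperature else temperature
  d <- if (is.null(dimensionality)) curve@dimensionality else dimensionality
  if (!is.finite(a) || a <= 0) stop("bead radius must be positive")
  if (!is.finite(Tk) || Tk <= 0) stop("temperature must be positive")
  if (!isTRUE(curve@smoothed))
    message("gserModuli: curve has not been smoothed; consider smoothMSD()")
  ok <- curve@lags > 0 & curve@msd > 0
  if (!all(ok)) {
    warning(sum(!ok), " non-positive MSD point(s) dropped before GSER")
  }
  lags <- curve@lags[ok]; msd <- curve@msd[ok]
  if (length(lags) < 3) stop("need at least 3 positive MSD points")
  lt <- log(lags); lm_ <- log(msd)
  dv <- .localDerivs(lt, lm_, halfWindow = halfWindow)
  bad <- !is.finite(dv[, 1]) | !is.finite(dv[, 2])
  if (any(bad)) {
    warning(sum(bad), " point(s) with non-finite log-derivative dropped")
    lags <- lags[!bad]; msd <- msd[!bad]; dv <- dv[!bad, , drop = FALSE]
  }
  alpha <- pmin(1, pmax(0, dv[, 1]))
  beta <- pmin(1, pmax(-1, dv[, 2]))
  msd3d <- msd * (3 / d) * 1e-12                 # um^2 -> m^2, 3D equivalent
  Gmag <- .kB * Tk / (pi * a * msd3d * gamma(1 + alpha))
  Gstar <- Gmag * exp(1i * pi * alpha / 2)
  if (correction) {
    p0 <- digamma(1 + alpha); p1 <- trigamma(1 + alpha)
    C <- 1 + (beta / 2) *
      complex(real = p1 + p0^2 - pi^2 / 4, imaginary = -pi * p0)
    # guard against a degenerate correction overwhelming the estimate
    C[Mod(C) < 0.2] <- 1
    Gstar <- Gstar / C
  }
  o <- order(1 / lags)
  methods::new("ModuliCurves",
               omega = (1 / lags)[o],
               Gp = pmax(Re(Gstar), 0)[o],
               Gpp = pmax(Im(Gstar), 0)[o],
               alpha = alpha[o],
               measured = rep(TRUE, length(lags)),
               beadRadius = a, temperature = Tk, omegaC = NA_real_)
}

#' @rdname vptRheo-accessors
setMethod("omegas", "ModuliCurves", function(x) x@omega)
#' @rdname vptRheo-accessors
setMethod("elasticModulus", "ModuliCurves", function(x) x@Gp)
#' @rdname vptRheo-accessors
setMethod("viscousModulus", "ModuliCurves", function(x) x@Gpp)
#' @rdname vptRheo-accessors
setMethod("localSlope", "ModuliCurves", function(x) x@alpha)
#' @rdname vptRheo-accessors
setMethod("isMeasured", "ModuliCurves", function(x) x@measured)

setMethod("show", "ModuliCurves", function(object) {
  cat(sprintf(
    "ModuliCurves: %d points, omega %.3g..%.3g rad/s (%d measured)\n",
    length(object@omega), min(object@omega), max(object@omega),
    sum(object@measured)))
  if (is.finite(object@omegaC))
    cat(sprintf("  crossover omega_c = %.4g rad/s\n", object@omegaC))
})

#' Frequency-dependent viscosity
#'
#' Pointwise \eqn{\eta(\omega) = G''(\omega)/\omega} over the measured
#' frequencies.
#'
#' @param moduli A \linkS4class{ModuliCurves}.
#' @return A \linkS4class{ViscositySpectrum} (plateau not yet detected).
#' @export
viscositySpectrum <- function(moduli) {
  stopifnot(is(moduli, "ModuliCurves"))
  if (!length(moduli@omega)) stop("empty moduli")
  m <- moduli@measured
  methods::new("ViscositySpectrum", omega = moduli@omega[m],
               eta = moduli@Gpp[m] / moduli@omega[m],
               plateauRange = c(NA_real_, NA_real_), eta0 = NA_real_,
               fromFit = FALSE)
}

#' @rdname vptRheo-accessors
setMethod("omegas", "ViscositySpectrum", function(x) x@omega)
#' @rdname vptRheo-accessors
setMethod("etaZero", "ViscositySpectrum", function(x) x@eta0)
#' @rdname vptRheo-accessors
setMethod("plateauRange", "ViscositySpectrum", function(x) x@plateauRange)

setMethod("show", "ViscositySpectrum", function(object) {
  cat(sprintf("ViscositySpectrum: %d points, omega %.3g..%.3g rad/s\n",
              length(object@omega), min(object@omega), max(object@omega)))
  if (is.finite(object@eta0))
    cat(sprintf("  eta0 = %.4g Pa s (plateau %.3g..%.3g rad/s%s)\n",
                object@eta0, object@plateauRange[1], object@plateauRange[2],
                if (object@fromFit) ", from Maxwell fit" else ""))
})

#' Zero-shear viscosity from the low-frequency plateau
#'
#' Finds the lowest-frequency maximal run of consecutive points with
#' \eqn{|d\ln\eta/d\ln\omega| <} \code{slopeTol} (at least \code{minRun}
#' points) and returns the mean viscosity over that run as \eqn{\eta_0}.
#' When no plateau is found and a \linkS4class{MaxwellFit} is supplied,
#' falls back to the fit's \eqn{G_0\tau}, flagged via \code{fromFit}.
#'
#' @param spectrum A \linkS4class{ViscositySpectrum} spanning at least one
#'   decade.
#' @param slopeTol Absolute log-log slope below which a point counts as
#'   flat.
#' @param minRun Minimum number of consecutive flat points.
#' @param fit Optional \linkS4class{MaxwellFit} fallback.
#' @return The input spectrum with \code{eta0}, \code{plateauRange} and
#'   \code{fromFit} filled in; read the estimate with
#'   \code{\link{etaZero}}.
#' @export
zeroShearViscosity <- function(spectrum, slopeTol = 0.1, minRun = 3,
                               fit = NULL) {
  stopifnot(is(spectrum, "ViscositySpectrum"))
  om <- spectrum@omega; eta <- spectrum@eta
  if (!length(om)) stop("empty viscosity spectrum")
  if (max(om) / min(om) < 10)
    stop("spectrum must span at least one decade")
  pos <- eta > 0
  sl <- rep(NA_real_, length(om))
  if (sum(pos) >= 3) {
    dv <- .localDerivs(log(om[pos]), log(eta[pos]), halfWindow = 2)
    sl[pos] <- dv[, 1]
  }
  flat <- is.finite(sl) & abs(sl) < slopeTol
  # maximal (longest) run of consecutive flat points; ties go to the
  # lowest-frequency run, where a terminal plateau lives
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  i <- NA_integer_; j <- NA_integer_
  if (length(cand)) {
    best <- cand[which.max(r$lengths[cand])]
    i <- starts[best]; j <- ends[best]
  }
  if (!is.na(i) && j - i + 1 >= minRun) {
    spectrum@eta0 <- mean(eta[i:j])
    spectrum@plateauRange <- c(om[i], om[j])
    spectrum@fromFit <- FALSE
  } else if (!is.null(fit)) {
    spectrum@eta0 <- fit@eta0
    spectrum@plateauRange <- c(NA_real_, NA_real_)
    spectrum@fromFit <- TRUE
    warning("no low-frequency plateau found; eta0 taken from Maxwell fit")
  } else {
    stop("no low-frequency plateau found and no Maxwell fit supplied")
  }
  spectrum
}

#' Terminal relaxation time from the first moduli crossover
#'
#' Locates the lowest-frequency crossing of \eqn{G' = G''} by log-log
#' linear interpolation between the bracketing measured points and returns
#' \eqn{\omega_c} and \eqn{\tau_{rel} = 1/\omega_c}.  When the crossing
#' lies outside the measured band and a \linkS4class{MaxwellFit} is
#' supplied, returns the fit's \eqn{1/\tau} flagged as extrapolated.  Any
#' additional crossings at higher frequency are reported in
#' \code{extraCrossovers}.
#'
#' @param moduli A \linkS4class{ModuliCurves}.
#' @param fit Optional \linkS4class{MaxwellFit} fallback.
#' @return List with \code{omegaC} (rad/s), \code{tauRel} (s),
#'   \code{extrapolated} and \code{extraCrossovers} (rad/s, possibly
#'   empty).
#' @export
crossoverTime <- function(moduli, fit = NULL) {
  stopifnot(is(moduli, "ModuliCurves"))
  m <- moduli@measured
  om <- moduli@omega[m]; Gp <- moduli@Gp[m]; Gpp <- moduli@Gpp[m]
  # log-ratio; G' = 0 counts as "below G''"
  r <- ifelse(Gp > 0 & Gpp > 0, log(Gp / Gpp), -Inf)
  up <- which(r[-length(r)] < 0 & r[-1] >= 0)
  crossAt <- function(i) {
    if (!is.finite(r[i])) return(om[i + 1])
    f <- -r[i] / (r[i + 1] - r[i])
    exp(log(om[i]) + f * (log(om[i + 1]) - log(om[i])))
  }
  if (length(up)) {
    wc <- crossAt(up[1])
    down <- which(r[-length(r)] >= 0 & r[-1] < 0)
    extra <- vapply(c(up[-1], down[down > up[1]]), crossAt, numeric(1))
    list(omegaC = wc, tauRel = 1 / wc, extrapolated = FALSE,
         extraCrossovers = sort(extra))
  } else if (!is.null(fit)) {
    list(omegaC = fit@omegaC, tauRel = fit@tau, extrapolated = TRUE,
         extraCrossovers = numeric(0))
  } else {
    stop("no crossover in measured band")
  }
}

# joint log-residuals of Maxwell moduli
.maxwellResid <- function(par, om, Gp, Gpp, useGp) {
  G0 <- exp(par[1]); tau <- exp(par[2])
  wt2 <- (om * tau)^2
  mp <- G0 * wt2 / (1 + wt2)
  mpp <- G0 * om * tau / (1 + wt2)
  c((log(Gp) - log(mp))[useGp], log(Gpp) - log(mpp))
}

#' @describeIn fitMaxwell Joint least squares of log G' and log G''
#'   against the Maxwell closed forms over the measured points.  Points
#'   with a non-positive modulus are excluded from that modulus's
#'   residuals; heavy exclusion, boundary parameters or a large residual
#'   raise the "model_mismatch" flag (Newtonian-like input is thereby
#'   detectable).
#' @param minPoints Minimum number of usable measured points.
#' @export
setMethod("fitMaxwell", "ModuliCurves", function(object, minPoints = 6) {
  m <- object@measured
  om <- object@omega[m]; Gp <- object@Gp[m]; Gpp <- object@Gpp[m]
  usable <- Gpp > 0
  if (sum(usable) < minPoints)
    stop("need at least ", minPoints, " measured points with G'' > 0")
  if (max(om[usable]) / min(om[usable]) < 10)
    stop("measured points must span at least one decade")
  om <- om[usable]; Gp <- Gp[usable]; Gpp <- Gpp[usable]
  useGp <- Gp > 0
  flags <- character(0)
  if (mean(useGp) < 0.7) flags <- c(flags, "few_elastic_points")
  # start values: G'' peaks at omega = 1/tau with height G0/2
  ipk <- which.max(Gpp)
  p0 <- c(log(2 * Gpp[ipk]), -log(om[ipk]))
  obj <- function(p) sum(.maxwellResid(p, om, Gp, Gpp, useGp)^2)
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt <- stats::optim(opt$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  G0 <- exp(opt$par[1]); tau <- exp(opt$par[2])
  nres <- sum(useGp) + length(om)
  residual <- sqrt(opt$value / nres) / log(10)   # rms log10 residual
  if (!is.finite(residual)) residual <- Inf
  converged <- opt$convergence == 0 && is.finite(residual)
  if (!converged) stop("Maxwell fit did not converge (residual ",
                       signif(residual, 3), ")")
  if (tau < 2 / max(om) * 1e-3 || tau > 2 / min(om) * 1e3)
    flags <- c(flags, "tau_at_bound")
  if (residual > 0.15) flags <- c(flags, "model_mismatch")
  methods::new("MaxwellFit", G0 = G0, tau = tau, eta0 = G0 * tau,
               omegaC = 1 / tau, residual = residual,
               converged = converged, flags = flags)
})

#' @describeIn fitMaxwell Time-domain entry point: the Maxwell MSD is
#'   offset-plus-linear, \eqn{\mathrm{MSD}_{2D}(t) = \frac{2}{3}
#'   \frac{k_BT}{\pi a}(1/G_0 + t/\eta_0)}, so a pair-count-weighted
#'   linear regression of MSD on lag yields G0 and eta0 directly
#'   (tau = intercept/slope ratio).
#' @export
setMethod("fitMaxwell", "MSDCurve", function(object, ...) {
  kT <- .kB * object@temperature
  a <- object@beadRadius
  if (!is.finite(a) || !is.finite(kT))
    stop("MSD curve lacks bead radius or temperature metadata")
  ok <- object@lags > 0 & object@msd > 0
  lags <- object@lags[ok]
  msd <- object@msd[ok] * 1e-12 / (2 / 3) * (pi * a) / kT   # back to J(t), 1/Pa
  w <- object@nObs[ok]
  if (!all(is.finite(w))) w <- rep(1, length(lags))
  fit <- stats::lm(msd ~ lags, weights = w)
  cf <- stats::coef(fit)
  if (cf[1] <= 0 || cf[2] <= 0)
    stop("MSD is not offset-plus-linear with positive coefficients; ",
         "Maxwell model rejected")
  G0 <- 1 / cf[1]; eta0 <- 1 / cf[2]
  methods::new("MaxwellFit", G0 = unname(G0), tau = unname(eta0 / G0),
               eta0 = unname(eta0), omegaC = unname(G0 / eta0),
               residual = sqrt(mean(stats::residuals(fit)^2)) /
                 mean(msd),
               converged = TRUE, flags = character(0))
})

#' @rdname vptRheo-accessors
setMethod("plateauModulus", "MaxwellFit", function(x) x@G0)
#' @rdname vptRheo-accessors
setMethod("relaxationTime", "MaxwellFit", function(x) x@tau)
#' @rdname vptRheo-accessors
setMethod("etaZero", "MaxwellFit", function(x) x@eta0)

setMethod("show", "MaxwellFit", function(object) {
  cat(sprintf(
    "MaxwellFit: G0 = %.4g Pa, tau = %.4g s, eta0 = %.4g Pa s\n",
    object@G0, object@tau, object@eta0))
  cat(sprintf("  omega_c = %.4g rad/s, rms log10 residual = %.3g%s\n",
              object@omegaC, object@residual,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ", "), "]")
              else ""))
})

#' Extend measured moduli with model extrapolation
#'
#' Appends Maxwell-model moduli at frequencies outside the measured band,
#' flagged as extrapolated (\code{measured = FALSE}), mirroring the usual
#' solid/dashed presentation of measured versus extrapolated moduli.
#'
#' @param moduli Measured \linkS4class{ModuliCurves}.
#' @param fit A \linkS4class{MaxwellFit}.
#' @param omegas Frequencies to add, rad/s; those inside the measured band
#'   are ignored.
#' @return A combined \linkS4class{ModuliCurves} with \code{omegaC} from
#'   the fit.
#' @export
extendModuli <- function(moduli, fit, omegas) {
  stopifnot(is(moduli, "ModuliCurves"), is(fit, "MaxwellFit"))
  band <- range(moduli@omega[moduli@measured])
  omegas <- sort(omegas[omegas < band[1] | omegas > band[2]])
  wt2 <- (omegas * fit@tau)^2
  Gp <- fit@G0 * wt2 / (1 + wt2)
  Gpp <- fit@G0 * omegas * fit@tau / (1 + wt2)
  alpha <- 1 / (1 + omegas * fit@tau)
  om <- c(moduli@omega, omegas)
  o <- order(om)
  methods::new("ModuliCurves", omega = om[o],
               Gp = c(moduli@Gp, Gp)[o], Gpp = c(moduli@Gpp, Gpp)[o],
               alpha = c(moduli@alpha, alpha)[o],
               measured = c(moduli@measured, rep(FALSE, length(omegas)))[o],
               beadRadius = moduli@beadRadius,
               temperature = moduli@temperature, omegaC = fit@omegaC)
}
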