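#' Log-log MSD plot
#'
#' @param curve An \linkS4class{MSDCurve}.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, NULL.
#' @export
plotMSD <- function(curve, ...) {
  graphics::plot(curve@lags, curve@msd, log = "xy", type = "l",
                 xlab = "lag time (s)",
                 ylab = expression(MSD ~ (mu * m^2)), ...)
  invisible(NULL)
}

#' Log-log moduli plot
#'
#' G' and G'' against frequency; measured points solid, extrapolated
#' dashed; the crossover frequency (when known) as a grey vertical line.
#'
#' @param moduli A \linkS4class{ModuliCurves}.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, NULL.
#' @export
plotModuli <- function(moduli, ...) {
  om <- moduli@omega
  pos <- pmax(c(moduli@Gp, moduli@Gpp), 1e-12)
  graphics::plot(NA, NA, log = "xy", xlim = range(om),
                 ylim = range(pos[pos > 1e-12]),
                 xlab = expression(omega ~ (rad / s)),
                 ylab = "modulus (Pa)", ...)
  m <- moduli@measured
  seg <- function(y, col) {
    graphics::lines(om[m], pmax(y[m], 1e-12), col = col, lty = 1)
    if (any(!m))
      graphics::lines(om[!m], pmax(y[!m], 1e-12), col = col, lty = 2)
  }
  seg(moduli@Gp, "firebrick")
  seg(moduli@Gpp, "steelblue")
  if (is.finite(moduli@omegaC))
    graphics::abline(v = moduli@omegaC, col = "grey", lty = 3)
  graphics::legend("bottomright", c("G'", "G''"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(NULL)
}

#' Viscosity-spectrum plot
#'
#' eta(omega) on log-log axes with the detected zero-shear plateau
#' shaded.
#'
#' @param spectrum A \linkS4class{ViscositySpectrum}.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, NULL.
#' @export
plotViscosity <- function(spectrum, ...) {
  graphics::plot(spectrum@omega, spectrum@eta, log = "xy", type = "l",
                 xlab = expression(omega ~ (rad / s)),
                 ylab = expression(eta ~ (Pa %.% s)), ...)
  pr <- spectrum@plateauRange
  if (all(is.finite(pr))) {
    usr <- graphics::par("usr")
    graphics::rect(pr[1], 10^usr[3], pr[2], 10^usr[4],
                   col = grDevices::adjustcolor("grey", 0.3), border = NA)
    graphics::abline(h = spectrum@eta0, col = "grey30", lty = 2)
  }
  invisible(NULL)
}
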