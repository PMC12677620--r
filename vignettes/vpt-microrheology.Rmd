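---
title: "Passive microrheology and image quantification of condensates with vptRheo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive microrheology and image quantification of condensates with vptRheo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vptRheo)
```

# The measurement

Micron-scale protein condensates -- such as reconstituted
pericentriolar-material (PCM) scaffolds -- are viscoelastic: they store
elastic stress on short time scales and flow on long ones.  Passive
video particle-tracking (VPT) microrheology infers this behaviour from
the thermal motion of tracer beads (100 nm diameter here) embedded in
the material.  The chain is:

1. **Track** beads in a video stream (15 ms/frame, at least 10,000
   frames) to sub-pixel accuracy, link detections into trajectories, and
   keep only beads near the condensate centre (boundary proximity
   suppresses the apparent mobility).
2. **Average**: the ensemble mean squared displacement (MSD)
   $\langle\Delta r^2(\tau)\rangle$ over log-spaced lag times,
   pair-count-weighted over all overlapping displacement pairs, smoothed
   with a moving average whose span stays below 10% of the series.
3. **Invert** via the generalized Stokes--Einstein relation (GSER) in
   Mason's local power-law form to the complex modulus
   $G^*(\omega) = G'(\omega) + i\,G''(\omega)$.
4. **Summarize**: the viscosity spectrum $\eta(\omega) = G''/\omega$,
   its low-frequency plateau (the zero-shear viscosity $\eta_0$), the
   first $G' = G''$ crossover (the terminal relaxation time
   $\tau_{rel} = 1/\omega_c$), and a single-mode Maxwell fit
   ($G_0$, $\tau$, $\eta_0 = G_0\tau$).

Companion modules quantify the imaging assays that usually accompany
such studies: FRAP recovery (one-phase fits with bootstrap confidence
intervals, in vitro reference-based and in vivo min--max normalization,
partial-bleach line scans), condensate segmentation (size, integrated
density, partition coefficients), and persistence curves for extrusion
and dilution assays.

# The synthetic generator is the test bed

No public bead-trajectory data accompany this kind of experiment, so the
package carries a generator whose outputs have closed-form expectations,
and every downstream stage is validated against those oracles.

A medium is either Newtonian ($\eta$) or a single-relaxation-time
Maxwell fluid, whose creep compliance is exactly

$$J(t) = \frac{1}{G_0} + \frac{t}{\eta_0}, \qquad G_0 = \eta_0/\tau,$$

giving the 2D tracer MSD

$$\langle\Delta r^2(t)\rangle = \frac{2}{3}\frac{k_BT}{\pi a}\,J(t).$$

Because this is offset-plus-linear, a Maxwell bead path can be sampled
*exactly* at all lags $\ge dt$ as free diffusion at the terminal
diffusivity $D_0 = k_BT/(6\pi\eta_0 a)$ plus independent per-frame
Gaussian "cage" jitter of per-axis variance $k_BT/(6\pi a G_0)$.  This
choice trades generality for exactness and speed: no generalized
Langevin integrator, no discretisation error, and the identity
(offset)/(slope) $= \tau$ holds in expectation at every lag.  What the
generator deliberately does *not* emulate: hydrodynamic memory (the
sub-$dt$ physics of a real Maxwell fluid), bead--bead interactions,
confinement unless asked (`dropletRadius`), and photobleaching inside
the tracking videos.  Passing tests therefore demonstrate the *analysis
chain* is correct and calibrated, not that real condensates are Maxwell
fluids.

Default study conditions mirror the acquisition they stand in for:
bead radius $a$ = 50 nm, $T$ = 303.15 K (samples incubated at 30 °C;
the temperature entering $k_BT$ is configurable because acquisition
temperature is rarely reported), $dt$ = 15 ms, 10,000 frames, 300
beads.  The two reference media are the phosphorylated and
unphosphorylated scaffold conditions, $(\eta_0, \tau)$ = (31.8 Pa s,
4.6 s) and (3.8 Pa s, 1.03 s).

Rendered videos (Gaussian PSF, Poisson photon noise, Gaussian read
noise) validate the tracking stage at low viscosity and high SNR, where
per-frame displacements are large compared with localization noise.
The headline rheology recoveries run on simulated trajectories
directly: at $\eta_0 \approx 32$ Pa s a bead moves about a nanometre
per frame, far below any realistic localization precision, exactly as
in the real experiment where the MSD near the noise floor is already
smoothed by averaging tens of thousands of trajectories.

```{r quickstart}
model <- mediumModel("maxwell", eta0 = 3.8, tau = 1.03)
traj <- simulateTrajectories(model, nBeads = 60, nFrames = 4000, seed = 1)
msd <- smoothMSD(ensembleMSD(traj, defaultLagGrid(0.015, 30)))
moduli <- gserModuli(msd)
fit <- fitMaxwell(moduli)
spectrum <- zeroShearViscosity(viscositySpectrum(moduli), fit = fit)
crossover <- crossoverTime(moduli, fit = fit)
c(eta0 = etaZero(spectrum), tau_rel = crossover$tauRel)
```

# The GSER estimator and its accuracy

Mason's inversion evaluates, at each lag $t$ with $\omega = 1/t$ and
$\alpha(\omega) = d\ln \mathrm{MSD}/d\ln t$ (clamped to $[0,1]$),

$$|G^*(\omega)| = \frac{k_BT}{\pi a\,\mathrm{MSD_{3D}}(1/\omega)\,
  \Gamma[1+\alpha]}, \qquad
  G' = |G^*|\cos\tfrac{\pi\alpha}{2},\;
  G'' = |G^*|\sin\tfrac{\pi\alpha}{2}.$$

The tracked MSD is two-dimensional and is converted to its 3D
equivalent by $\times 3/2$ before the formula (configurable via
`dimensionality`).

The pure power-law approximation is exact for a Newtonian fluid but
errs by roughly 20% where the MSD curves in log--log space -- precisely
at the Maxwell crossover that defines $\tau_{rel}$.  `gserModuli`
therefore carries a second-order correction by default: modelling the
MSD locally as a log-parabola with curvature
$\beta = d^2\ln\mathrm{MSD}/d(\ln t)^2$ and transforming that model
exactly to first order in $\beta$ divides $G^*$ by

$$C = 1 + \frac{\beta}{2}\left[\psi_1(1{+}\alpha) + \psi_0(1{+}\alpha)^2
  - \frac{\pi^2}{4} - i\pi\,\psi_0(1{+}\alpha)\right],$$

with $\psi_0, \psi_1$ the digamma and trigamma functions.  Verified
against closed-form Maxwell moduli over the band
$0.1\,\omega_c$--$10\,\omega_c$ (the test suite asserts these bounds),
the corrected estimator keeps $G'$ within 10%, both moduli within 5% of
$|G^*|$ pointwise and within 5% of themselves over the central decade,
and the moduli at the crossover within 15% of $G_0/2$; the *minor*
modulus at the extreme band edges can still deviate by up to ~20% of
its (small) value.  That
residual is a locality limit: the information about $G''$ at
$10\,\omega_c$ lives in a tiny linear term on top of the MSD plateau,
and no pointwise estimator resolves it; still-higher-order local
corrections amplify measurement noise faster than they reduce bias (a
third/fourth-order variant was tested and rejected on that ground).
Consumers who need the minor component at band edges should read it
from the Maxwell fit instead.

One subtlety is worth knowing: the *uncorrected* estimator locates the
Maxwell $G'=G''$ crossover exactly (at $\alpha = 1/2$ its phase is
$\pi/4$ by symmetry), while the corrected one shifts it by 2--4% but
gets the moduli magnitudes right.  `correction = FALSE` restores the
textbook estimator when the crossover location alone matters.

Derivatives ($\alpha$, $\beta$) come from local quadratic fits over
±4 grid points in log--log space, tolerant of the non-uniform spacing
produced by snapping lags to integer frame multiples; $\beta$ is
clamped to $[-1, 1]$ and the correction is skipped wherever $|C|$
would fall below 0.2.

# Estimator conventions and numerical choices

* **Lag grid**: 20 points per decade, 0.015--100 s.  Lags snap to
  integer frame multiples; lags longer than every trajectory are
  dropped with a warning.
* **MSD averaging**: all overlapping pairs, weighted by pair count
  (the grand mean over pairs), so long trajectories count
  proportionately to the displacement pairs they contribute.
  Trajectories with linking gaps contribute only observed pairs.
* **Smoothing**: centred moving average in log-lag index space,
  `spanFraction` < 0.1 (default 0.08), shrunken windows at the ends.
* **Zero-shear plateau**: the longest run of at least 3 consecutive
  points with $|d\ln\eta/d\ln\omega| < 0.1$ (ties resolved towards low
  frequency); $\eta_0$ is the mean viscosity over the run.  With noisy
  long-lag MSDs no run may qualify; the estimator then falls back to
  the Maxwell fit's $G_0\tau$ and says so (`fromFit`).
* **Crossover**: lowest-frequency upward crossing of
  $\log(G'/G'')$, log--log interpolated; outside the measured band the
  Maxwell fit supplies it, flagged extrapolated.  Additional crossings
  (a second crossover at high frequency, where one is suspected but not
  measurable by VPT) are reported but not modelled.
* **Maxwell fit**: joint least squares of $\log G'$ and $\log G''$
  over measured points, optimised over $(\log G_0, \log\tau)$
  (Nelder--Mead then BFGS); points with a non-positive modulus are
  excluded from that modulus's residuals.  A Newtonian input is
  detectable: $\tau$ runs to a bound and the fit is flagged.  An
  MSD-space entry point (`fitMaxwell` on an `MSDCurve`) exploits the
  offset-plus-linear form as a weighted linear regression; moduli-space
  is the default because that is where such fits are conventionally
  shown.
* **Tracking defaults** (none are reported for the original analysis;
  these are declared, not inferred): feature diameter 7 px, maximum
  displacement 5 px, linking memory 3 frames, minimum length 100
  frames.  Sub-pixel refinement is iterative intensity-weighted
  centroiding (cap 10 iterations), the Crocker--Grier lineage rather
  than Gaussian fitting.  Linking assigns candidate pairs greedily by
  increasing displacement, a near-optimal proxy for the
  minimum-total-squared-displacement assignment at tracking densities
  where steps are far smaller than spacings.
* **Static error**: stationary-bead fixtures report the localization
  MSD offset $4\sigma_{loc}^2$ (`staticErrorOffset`); it is *not*
  subtracted by default, matching the conventional analysis, and the
  rheology fixtures operate far above or below it by design.
* **FRAP fitting**: $I(t) = p(1 - e^{-kt})$ with $I(0)$ fixed at 0 --
  both normalization conventions force the first post-bleach value to
  the floor, so an offset would be unidentifiable.  Initialisation
  profiles the (conditionally linear) plateau over a log-spaced $k$
  grid before Levenberg--Marquardt, which keeps weakly identified
  fits (slow, shallow recoveries) from running along the likelihood
  valley to a bound.  Confidence intervals use a residual bootstrap
  calibrated for 8-point traces: residuals are centred and inflated by
  $\sqrt{n/(n-2)}$ (they are variance-shrunken by the 2-parameter
  fit), and intervals are $\hat\theta \pm t_{0.975,n-2}\,
  \mathrm{sd}(\theta^*)$; the suite verifies at least 90% coverage of
  the generative plateau over 200 synthetic replicates, which the
  plain percentile bootstrap did not reach on such short traces.
  Both the fitted plateau and the last-timepoint value are reported,
  since descriptive "recovery up to X%" statements can mean either.
* **Segmentation**: 3 px median filter, Otsu threshold (with a
  background floor of median + 3 MAD so an empty field yields no
  objects; a fixed threshold is available for strict reproducibility),
  optional distance-transform watershed for chains of touching
  condensates, minimum object size 9 px.  Integrated density is the
  raw pixel sum (so mean × area holds exactly); a background-subtracted
  variant (frame median of non-object pixels) is reported alongside,
  and partition coefficients exclude a 2 px dilated rim around every
  object to avoid PSF bleed into the dilute phase.  Images with
  z-stacks should be maximum-projected first; projection versus
  z-summation changes integrated densities by a scale factor that
  cancels in every normalized quantity.

# Problem sizes used in validation

The validation suite simulates 300 beads × 10,000 frames per condition
and seed for the headline recoveries (three seeds each), 16-bead
300-frame rendered videos for the tracking round trip, 200 synthetic
replicates for bootstrap-coverage calibration, and 10--12 object fields
across 10 seeds for segmentation recovery.  These sizes reproduce the
generative parameters to well within the tolerances asserted (typically
a few percent for $\eta_0$ and $\tau_{rel}$); enlarging them tightens
the estimates as $1/\sqrt{n}$ without changing any conclusion.

# Known limitations

* The GSER inversion assumes an unconfined, homogeneous, incompressible
  medium and ignores inertia -- the usual passive one-point
  assumptions.  No confinement correction is applied; instead,
  centre-of-condensate filtering discards the beads where confinement
  bites.
* The minor modulus near band edges inherits the locality error
  discussed above (bounded at 20% in the suite).
* The Maxwell model is single-mode; materials with spectra broader
  than one relaxation time will show a flagged large-residual fit
  rather than a second mode.
* One-phase FRAP fitting does not model diffusion during bleach,
  bleach-spot geometry, or two-component recovery; the partial-bleach
  line-scan readout is deliberately descriptive (normalized landmark
  intensities), not a reaction--diffusion fit.
* Segmentation is 2D.  Anisotropic PSFs, uneven illumination beyond a
  median background, and fusion-event detection are out of scope.
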