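# vptRheo

Video particle-tracking (VPT) microrheology and image quantification for
biomolecular condensates, written for the workflow used to characterise
reconstituted pericentriolar-material (PCM) scaffolds: infer a
condensate's viscoelasticity from the thermal motion of embedded 100 nm
tracer beads, and quantify the FRAP, segmentation, partition and
persistence assays that accompany such measurements.

## Who this is for

Labs doing passive one-point microrheology on protein droplets (or any
soft material seeded with fluorescent tracers) who want a tested,
scriptable chain from raw TIFF videos — or from trajectory tables — to
the standard summary numbers: the elastic and viscous moduli
G′(ω)/G″(ω), the zero-shear viscosity η₀, and the terminal relaxation
time τ_rel.

## The method in brief

1. **Tracking** (Crocker–Grier style): bandpass filtering, sub-pixel
   centroid localization, greedy nearest-candidate linking with gap
   memory, and centre-of-condensate filtering.
2. **Ensemble MSD**: time-averaged over all overlapping displacement
   pairs, pair-count weighted, on a log-spaced lag grid (default
   0.015–100 s), then moving-average smoothed.
3. **GSER inversion** (Mason's local power-law method): with
   α(ω) = d ln MSD/d ln t at t = 1/ω,

       |G*(ω)| = kT / (π a · MSD₃D(1/ω) · Γ[1+α]),
       G′ = |G*| cos(πα/2),  G″ = |G*| sin(πα/2),

   plus a second-order log-curvature correction (see the vignette) that
   keeps the estimate within a few percent of closed forms at spectral
   transitions.
4. **Summaries**: η(ω) = G″/ω and its low-frequency plateau mean (η₀);
   the first G′ = G″ crossover (τ_rel = 1/ω_c); and a Maxwell-fluid fit
   G′ = G₀ω²τ²/(1+ω²τ²), G″ = G₀ωτ/(1+ω²τ²), with η₀ = G₀τ.

Companion modules: one-phase FRAP fitting I(t) = p(1−e^(−kt)) with
calibrated bootstrap CIs and both in vitro (reference condensate) and in
vivo (min–max) normalization conventions; threshold/watershed condensate
segmentation with size, integrated density and partition-coefficient
statistics; persistence curves for extrusion/dilution assays; and a
Brownian-dynamics generator of bead motion in Newtonian and Maxwell
media with closed-form oracles, which is what makes the whole chain
testable without any external data.

## Worked example

Simulate beads in a Maxwell medium parameterized like a phosphorylated
PCM condensate (η₀ = 31.8 Pa s, τ = 4.6 s), then recover those numbers
with the full analysis chain:

```r
library(vptRheo)

model <- mediumModel("maxwell", eta0 = 31.8, tau = 4.6)
model
#> MediumModel: maxwell, eta0 = 31.8 Pa s, tau = 4.6 s (G0 = 6.91304 Pa)
#>   T = 303.15 K, bead radius = 50 nm, D = 0.0001397 um^2/s

traj <- simulateTrajectories(model, nBeads = 300, nFrames = 10000, seed = 1)
msd <- smoothMSD(ensembleMSD(traj))
moduli <- gserModuli(msd)
fit <- fitMaxwell(moduli)
fit
#> MaxwellFit: G0 = 6.655 Pa, tau = 4.964 s, eta0 = 33.04 Pa s
#>   omega_c = 0.2014 rad/s, rms log10 residual = 0.107

spectrum <- zeroShearViscosity(viscositySpectrum(moduli), fit = fit)
cross <- crossoverTime(moduli, fit = fit)
sprintf("eta0 = %.1f Pa s, tau_rel = %.2f s", etaZero(spectrum), cross$tauRel)
#> [1] "eta0 = 33.0 Pa s, tau_rel = 4.39 s"
```

The generative η₀ = 31.8 Pa s comes back as 33.0 (here via the Maxwell
fit — this realization's long-lag MSD is too wobbly for the plateau
detector, which the object flags) and τ = 4.6 s as 4.39 s; medians over
a few seeds land within ~5%. A FRAP trace at a 20% mobile fraction,
sampled every 20 s to 140 s:

```r
tr <- simulateFrapTrace(0.20, 0.02, noiseSd = 0.01, seed = 2)
fitOnePhase(tr, seed = 3)
#> FRAPFit: plateau (mobile fraction) = 0.197, k = 0.02124 /s, t1/2 = 32.6 s
#>   95% CI plateau [0.172, 0.223], k [0.0141, 0.02838]
#>   recovery at last point = 0.185
```

`plotMSD()`, `plotModuli()` and `plotViscosity()` draw the standard
log–log panels (measured solid, extrapolated dashed, plateau shaded).
A YAML-configured front end chains the stages
(`runPipeline("all", "run.yaml")`; a thin CLI wrapper lives in
`inst/scripts/vpt-pipeline.R`).

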