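test_that("ensemble MSD follows its definition and pair-count weighting", {
  # single two-point trajectory: MSD(dt) = dx^2 + dy^2
  m <- mediumModel("newtonian", eta = 1)
  traj <- simulateTrajectories(m, nBeads = 1, nFrames = 2, seed = 1)
  d <- trajectories(traj)
  d$x_um <- c(0, 0.3); d$y_um <- c(0, -0.4)
  traj@data <- d
  est <- ensembleMSD(traj, 0.015)
  expect_equal(msdValues(est), 0.3^2 + 0.4^2)
  expect_equal(msdCounts(est), 1)

  # default lag grid endpoints: 0.015 to 100 s
  g <- defaultLagGrid()
  expect_equal(range(g), c(0.015, 100))
  expect_true(all(diff(log(g)) > 0))

  # lags beyond every trajectory span are dropped with a warning
  expect_warning(ensembleMSD(traj, c(0.015, 10)), "exceed")

  # trajectories with gaps contribute only observed pairs
  gappy <- simulateTrajectories(m, nBeads = 1, nFrames = 5, seed = 1)
  dg <- trajectories(gappy)
  dg$x_um <- c(0, 1, 2, 3, 4); dg$y_um <- 0
  dg <- dg[dg$frame != 2, ]
  gappy@data <- dg
  est2 <- ensembleMSD(gappy, 0.015)
  expect_equal(msdCounts(est2), 2)   # pairs (0,1) and (3,4) only
  expect_equal(msdValues(est2), 1)
})

test_that("ensemble MSD of simulated newtonian beads is 4 D per unit lag", {
  m <- mediumModel("newtonian", eta = 0.02)
  D <- seDiffusivity(0.02)
  traj <- simulateTrajectories(m, nBeads = 300, nFrames = 2000, seed = 21)
  est <- ensembleMSD(traj, c(1, 2, 4, 8) * 0.015)
  ratio <- msdValues(est) / msdLags(est)
  # within 3 standard errors of 4D (per-lag SE ~ sqrt(2/nIndep) * 4D)
  se <- 4 * D * sqrt(2 / (300 * 2000 / (msdLags(est) / 0.015)))
  expect_true(all(abs(ratio - 4 * D) < 3 * se / msdLags(est) * msdLags(est)))
  expect_lt(max(abs(ratio / (4 * D) - 1)), 0.05)
})

test_that("MSD smoothing is centred, monotone-preserving and denoising", {
  m <- caModel()
  curve <- analyticMSD(m, defaultLagGrid())
  n <- length(msdLags(curve))

  # smallest window: identity with a warning
  tiny <- curve
  expect_warning(sm0 <- smoothMSD(tiny, 0.01), "fewer than 3")
  expect_equal(msdValues(sm0), msdValues(curve))
  expect_error(smoothMSD(curve, 0.2), "spanFraction")

  # monotone input stays monotone
  sm <- smoothMSD(curve, 0.08)
  expect_true(all(diff(msdValues(sm)) > 0))
  expect_equal(msdLags(sm), msdLags(curve))

  # noisy curve moves closer to the oracle after smoothing
  set.seed(7)
  noisy <- curve
  noisy@msd <- noisy@msd * exp(rnorm(n, sd = 0.05))
  noisy@smoothed <- FALSE
  smn <- smoothMSD(noisy, 0.08)
  rmse <- function(x) sqrt(mean((log(x) - log(msdValues(curve)))^2))
  expect_lt(rmse(msdValues(smn)), rmse(msdValues(noisy)))
})

test_that("GSER inversion reproduces closed-form moduli", {
  lags <- defaultLagGrid()
  # newtonian: alpha = 1 everywhere, G'' = eta omega, G' ~ 0
  mn <- mediumModel("newtonian", eta = 1)
  gn <- gserModuli(analyticMSD(mn, lags))
  expect_true(all(abs(localSlope(gn) - 1) < 1e-6))
  om <- omegas(gn)
  central <- om > 0.1 & om < 10
  expect_lt(max(abs(viscousModulus(gn)[central] / om[central] - 1)), 0.03)
  expect_lt(max(elasticModulus(gn) / viscousModulus(gn)), 1e-6)

  # maxwell: moduli at the crossover within 15% of G0/2
  mm <- caModel()
  gm <- gserModuli(analyticMSD(mm, lags))
  G0 <- plateauModulus(mm)
  atWc <- function(y) stats::approx(log(omegas(gm)), y,
                                    xout = log(1 / 4.6))$y
  expect_equal(atWc(elasticModulus(gm)), G0 / 2, tolerance = 0.15)
  expect_equal(atWc(viscousModulus(gm)), G0 / 2, tolerance = 0.15)

  # constant MSD (pure plateau): alpha = 0, G' = kT/(pi a MSD3D), G'' ~ 0
  plateau <- analyticMSD(mm, lags)
  plateau@msd <- rep(2.5e-3, length(lags))
  gp <- gserModuli(plateau)
  expect_true(all(abs(localSlope(gp)) < 1e-9))
  Gexp <- kB * 303.15 / (pi * 50e-9 * 2.5e-3 * 1.5 * 1e-12)
  expect_equal(elasticModulus(gp), rep(Gexp, length(lags)),
               tolerance = 1e-6)
  expect_lt(max(viscousModulus(gp) / elasticModulus(gp)), 1e-6)
})

test_that("GSER round trip stays within the estimator's accuracy envelope", {
  # measured accuracy of the curvature-corrected local estimator over
  # 0.1-10 omega_c: dominant modulus and |G*| within a few percent; the
  # minor modulus degrades towards the band edge (locality limit)
  for (mm in list(caModel(), kdModel())) {
    tau <- relaxationTime(mm); G0 <- plateauModulus(mm)
    g <- gserModuli(analyticMSD(mm, defaultLagGrid()))
    om <- omegas(g)
    band <- om >= 0.1 / tau & om <= 10 / tau
    Gpt <- maxwellGp(G0, tau, om[band])
    Gppt <- maxwellGpp(G0, tau, om[band])
    magT <- sqrt(Gpt^2 + Gppt^2)
    expect_lt(max(abs(elasticModulus(g)[band] - Gpt) / magT), 0.05)
    expect_lt(max(abs(viscousModulus(g)[band] - Gppt) / magT), 0.05)
    expect_lt(max(abs(viscousModulus(g)[band] / Gppt - 1)), 0.20)
    expect_lt(max(abs(elasticModulus(g)[band] / Gpt - 1)), 0.10)
    # within the central decade both moduli are within 5% pointwise
    mid <- om >= 1 / tau / sqrt(10) & om <= sqrt(10) / tau
    expect_lt(max(abs(elasticModulus(g)[mid] /
                        maxwellGp(G0, tau, om[mid]) - 1)), 0.05)
    expect_lt(max(abs(viscousModulus(g)[mid] /
                        maxwellGpp(G0, tau, om[mid]) - 1)), 0.05)
  }
})

test_that("moduli scale as kT and inversely with bead radius", {
  mm <- caModel()
  curve <- analyticMSD(mm, defaultLagGrid())
  base <- gserModuli(curve)
  halfA <- gserModuli(curve, beadRadius = 25e-9)
  expect_equal(viscousModulus(halfA), 2 * viscousModulus(base),
               tolerance = 1e-9)
  warmer <- gserModuli(curve, temperature = 2 * 303.15)
  expect_equal(elasticModulus(warmer), 2 * elasticModulus(base),
               tolerance = 1e-9)
})

test_that("viscosity spectrum matches closed forms and is monotone for maxwell", {
  mm <- kdModel()
  om <- exp(seq(log(0.01), log(50), length.out = 80))
  spec <- viscositySpectrum(analyticModuli(mm, om))
  eta <- spec@eta
  # closed form eta(omega) = G0 tau / (1 + omega^2 tau^2), non-increasing
  expect_equal(eta, 3.8 / (1 + (om * 1.03)^2), tolerance = 1e-12)
  expect_true(all(diff(eta) <= 0))
  # eta at the crossover equals eta0/2
  expect_equal(stats::approx(log(om), eta, xout = log(1 / 1.03))$y,
               3.8 / 2, tolerance = 1e-3)

  # newtonian: constant
  sn <- viscositySpectrum(analyticModuli(mediumModel("newtonian", eta = 2),
                                         om))
  expect_equal(sn@eta, rep(2, 80), tolerance = 1e-12)
})

test_that("zero-shear viscosity comes from the low-frequency plateau", {
  # maxwell oracle sampled down to omega = 0.01/tau: within 2% of G0 tau
  mm <- caModel()
  om <- exp(seq(log(0.01 / 4.6), log(10), length.out = 120))
  sp <- zeroShearViscosity(viscositySpectrum(analyticModuli(mm, om)))
  expect_equal(etaZero(sp), 31.8, tolerance = 0.02)
  expect_false(sp@fromFit)
  expect_true(all(is.finite(plateauRange(sp))))

  # newtonian: eta0 = eta exactly, all points in the plateau
  om2 <- exp(seq(log(0.1), log(100), length.out = 50))
  sn <- zeroShearViscosity(viscositySpectrum(
    analyticModuli(mediumModel("newtonian", eta = 5), om2)))
  expect_equal(etaZero(sn), 5, tolerance = 1e-12)
  expect_equal(plateauRange(sn), range(om2))

  # no plateau, no fit: error; with fit: flagged fallback
  high <- viscositySpectrum(analyticModuli(mm, exp(seq(log(10 / 4.6),
    log(400), length.out = 30))))
  expect_error(zeroShearViscosity(high), "plateau")
  fit <- fitMaxwell(analyticModuli(mm, om))
  expect_warning(hf <- zeroShearViscosity(high, fit = fit), "Maxwell fit")
  expect_true(hf@fromFit)
  expect_equal(etaZero(hf), 31.8, tolerance = 1e-6)
})

test_that("crossover location and fallback behave as specified", {
  mm <- caModel()
  lags <- defaultLagGrid()
  # uncorrected local estimator: Maxwell crossover is exact (alpha = 1/2
  # phase symmetry); interpolation tolerance 1%
  cr0 <- crossoverTime(gserModuli(analyticMSD(mm, lags),
                                  correction = FALSE))
  expect_equal(cr0$tauRel, 4.6, tolerance = 0.01)
  expect_false(cr0$extrapolated)
  expect_equal(cr0$omegaC * cr0$tauRel, 1)

  # corrected default stays within a few percent
  cr1 <- crossoverTime(gserModuli(analyticMSD(mm, lags)))
  expect_equal(cr1$tauRel, 4.6, tolerance = 0.05)

  # newtonian: no elasticity, no crossover
  gn <- gserModuli(analyticMSD(mediumModel("newtonian", eta = 1), lags))
  expect_error(crossoverTime(gn), "no crossover")

  # crossover outside the measured band: fit fallback, flagged
  lowBand <- analyticModuli(mm, exp(seq(log(0.001), log(0.05),
                                        length.out = 30)))
  fit <- fitMaxwell(analyticModuli(mm, exp(seq(log(0.01), log(10),
                                               length.out = 60))))
  cf <- crossoverTime(lowBand, fit = fit)
  expect_true(cf$extrapolated)
  expect_equal(cf$tauRel, 4.6, tolerance = 1e-6)
})

test_that("Maxwell fitting recovers parameters and flags mismatch", {
  om <- exp(seq(log(0.01), log(10), length.out = 60))
  mm <- caModel()
  # oracle moduli: exact recovery
  fit <- fitMaxwell(analyticModuli(mm, om))
  expect_equal(plateauModulus(fit), 31.8 / 4.6, tolerance = 1e-6)
  expect_equal(relaxationTime(fit), 4.6, tolerance = 1e-6)
  expect_equal(etaZero(fit), plateauModulus(fit) * relaxationTime(fit))
  expect_equal(fit@omegaC * fit@tau, 1)

  # 5% multiplicative noise, 50 replicates: median recovery within 5%
  set.seed(31)
  rec <- vapply(1:50, function(i) {
    noisy <- analyticModuli(mm, om)
    noisy@Gp <- noisy@Gp * exp(rnorm(60, sd = 0.05))
    noisy@Gpp <- noisy@Gpp * exp(rnorm(60, sd = 0.05))
    f <- fitMaxwell(noisy)
    c(f@G0, f@tau)
  }, numeric(2))
  expect_equal(stats::median(rec[1, ]), 31.8 / 4.6, tolerance = 0.05)
  expect_equal(stats::median(rec[2, ]), 4.6, tolerance = 0.05)

  # newtonian moduli: tau driven to a bound and flagged
  gn <- gserModuli(analyticMSD(mediumModel("newtonian", eta = 1),
                               defaultLagGrid()))
  fn <- fitMaxwell(gn)
  expect_true(any(c("tau_at_bound", "model_mismatch",
                    "few_elastic_points") %in% fn@flags))

  # MSD-space entry point agrees exactly on the oracle
  fmsd <- fitMaxwell(analyticMSD(mm, defaultLagGrid()))
  expect_equal(plateauModulus(fmsd), 31.8 / 4.6, tolerance = 1e-9)
  expect_equal(relaxationTime(fmsd), 4.6, tolerance = 1e-9)
})

test_that("extended moduli flag extrapolated points", {
  mm <- kdModel()
  om <- exp(seq(log(0.1), log(10), length.out = 40))
  mo <- gserModuli(analyticMSD(mm, 1 / rev(om)))
  fit <- fitMaxwell(mo)
  ext <- extendModuli(mo, fit, c(0.001, 0.01, 100, 1000))
  expect_identical(sum(!isMeasured(ext)), 4L)
  expect_true(all(diff(omegas(ext)) > 0))
  expect_equal(ext@omegaC, fit@omegaC)
  # extrapolated values follow the fitted closed form
  lowest <- which.min(omegas(ext))
  expect_equal(viscousModulus(ext)[lowest],
               maxwellGpp(fit@G0, fit@tau, omegas(ext)[lowest]),
               tolerance = 1e-9)
})

test_that("the full chain recovers generative parameters at reduced scale", {
  # scaled-down parameter recovery (acceptance runs the full size)
  mm <- kdModel()
  traj <- simulateTrajectories(mm, nBeads = 100, nFrames = 5000, seed = 3)
  msd <- smoothMSD(ensembleMSD(traj, defaultLagGrid(0.015, 50)))
  mod <- gserModuli(msd)
  fit <- fitMaxwell(mod)
  sp <- suppressWarnings(zeroShearViscosity(viscositySpectrum(mod),
                                            fit = fit))
  cr <- crossoverTime(mod, fit = fit)
  expect_equal(etaZero(sp), 3.8, tolerance = 0.25)
  expect_equal(cr$tauRel, 1.03, tolerance = 0.25)
})
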