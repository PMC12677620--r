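test_that("analytic MSD matches Stokes-Einstein closed forms", {
  # newtonian: MSD(t) = 4 D t with D = kT/(6 pi eta a)
  m <- mediumModel("newtonian", eta = 1e-3)
  D <- seDiffusivity(1e-3)
  expect_equal(D, 4.4409, tolerance = 1e-4)
  expect_equal(msdValues(analyticMSD(m, 1)), 4 * D, tolerance = 1e-12)
  expect_equal(msdValues(analyticMSD(m, c(0.5, 2))), 4 * D * c(0.5, 2),
               tolerance = 1e-12)

  # maxwell: offset (2/3) kT/(pi a G0) as lag -> 0+
  mm <- caModel()
  G0 <- 31.8 / 4.6
  offset <- (2 / 3) * kB * 303.15 / (pi * 50e-9 * G0) * 1e12
  expect_equal(offset, 2.570e-3, tolerance = 1e-3)
  expect_equal(msdValues(analyticMSD(mm, 1e-9)), offset, tolerance = 1e-6)

  # zero lag is zero displacement
  expect_identical(msdValues(analyticMSD(mm, c(0, 1)))[1], 0)

  # non-physical parameters are rejected
  expect_error(mediumModel("maxwell", eta0 = -1, tau = 2), "eta0")
  expect_error(mediumModel("newtonian"), "eta")
  expect_error(analyticMSD(mm, c(2, 1)), "sorted")
})

test_that("analytic moduli honour the Maxwell identities", {
  m <- caModel()
  G0 <- plateauModulus(m)
  # crossover symmetry: G'(1/tau) = G''(1/tau) = G0/2
  mo <- analyticModuli(m, 1 / 4.6)
  expect_equal(elasticModulus(mo), G0 / 2, tolerance = 1e-12)
  expect_equal(viscousModulus(mo), G0 / 2, tolerance = 1e-12)
  expect_equal(mo@omegaC, 1 / 4.6)

  # zero-shear limit: G''/omega -> eta0
  lowOm <- 1e-5
  mo2 <- analyticModuli(m, lowOm)
  expect_equal(viscousModulus(mo2) / lowOm, 31.8, tolerance = 1e-6)

  # newtonian definition
  mn <- analyticModuli(mediumModel("newtonian", eta = 1), 10)
  expect_identical(elasticModulus(mn), 0)
  expect_equal(viscousModulus(mn), 10)
})

test_that("trajectory simulation is seed-deterministic", {
  m <- kdModel()
  a <- simulateTrajectories(m, nBeads = 5, nFrames = 200, seed = 7)
  b <- simulateTrajectories(m, nBeads = 5, nFrames = 200, seed = 7)
  expect_identical(trajectories(a), trajectories(b))
  c <- simulateTrajectories(m, nBeads = 5, nFrames = 200, seed = 8)
  expect_false(identical(trajectories(a), trajectories(c)))
  # confinement and rendering are deterministic too
  d1 <- simulateTrajectories(m, nBeads = 3, nFrames = 50, seed = 1,
                             dropletRadius = 2)
  d2 <- simulateTrajectories(m, nBeads = 3, nFrames = 50, seed = 1,
                             dropletRadius = 2)
  expect_identical(trajectories(d1), trajectories(d2))
})

test_that("sampled ensemble MSD converges to the analytic curve", {
  # newtonian and maxwell, three seeds, at lags with plentiful samples
  for (m in list(mediumModel("newtonian", eta = 0.05), kdModel())) {
    for (seed in 1:3) {
      traj <- simulateTrajectories(m, nBeads = 100, nFrames = 3000,
                                   dt = 0.015, seed = seed)
      lags <- (c(1, 2, 5, 10, 20, 50)) * 0.015
      est <- ensembleMSD(traj, lags)
      truth <- msdValues(analyticMSD(m, msdLags(est)))
      relErr <- abs(msdValues(est) / truth - 1)
      expect_lt(max(relErr[msdCounts(est) >= 1000]), 0.05)
    }
  }
})

test_that("maxwell sampled MSD has offset/slope ratio tau and an exact pure-elastic limit", {
  m <- kdModel()
  traj <- simulateTrajectories(m, nBeads = 200, nFrames = 3000, seed = 11)
  lags <- (1:60) * 0.015
  est <- ensembleMSD(traj, lags)
  fit <- stats::lm(msdValues(est) ~ msdLags(est))
  tauHat <- unname(coef(fit)[1] / coef(fit)[2])
  expect_equal(tauHat, 1.03, tolerance = 0.1)

  # eta0 -> Inf limit: MSD flat at the cage offset
  frozen <- simulateTrajectories(m, nBeads = 200, nFrames = 1000, seed = 2,
                                 diffusionOff = TRUE)
  estF <- ensembleMSD(frozen, c(0.015, 0.15, 1.5))
  offset <- (2 / 3) * kB * 303.15 / (pi * 50e-9 * plateauModulus(m)) * 1e12
  expect_equal(msdValues(estF), rep(offset, 3), tolerance = 0.05)
  expect_lt(diff(range(msdValues(estF))) / offset, 0.05)
})

test_that("confinement validates and flattens the long-lag MSD", {
  m <- mediumModel("newtonian", eta = 1e-3)
  expect_error(simulateTrajectories(m, nBeads = 2, nFrames = 10, seed = 1,
                                    dropletRadius = 0.01),
               "per-frame step")
  conf <- simulateTrajectories(m, nBeads = 100, nFrames = 500, seed = 3,
                               dropletRadius = 2)
  est <- ensembleMSD(conf, c(0.015, 3))
  free <- 4 * seDiffusivity(1e-3) * 3
  # confined MSD saturates well below free diffusion at long lags
  expect_lt(msdValues(est)[2], free / 2)
  expect_lt(msdValues(est)[2], 2 * 2^2)   # bounded by droplet size
})

test_that("rendered videos reflect the photon model", {
  traj <- staticBead(0, 0, nFrames = 1)
  # empty field: background + read noise only
  rv0 <- renderVideo(traj, peakSignal = 0, background = 50,
                     readNoiseSd = 3, imageShape = c(64, 64), seed = 2)
  px <- rv0$stack@pixels[, , 1]
  expect_equal(mean(px), 50, tolerance = 0.02)
  expect_equal(stats::sd(px), sqrt(50 + 9), tolerance = 0.1)

  # doubling peak signal doubles the integrated spot intensity
  tot <- vapply(c(500, 1000), function(ps) {
    rv <- renderVideo(traj, peakSignal = ps, background = 10,
                      readNoiseSd = 0, imageShape = c(64, 64), seed = 4)
    sum(rv$stack@pixels[, , 1]) - 10 * 64^2
  }, numeric(1))
  expect_equal(tot[2] / tot[1], 2, tolerance = 0.05)

  # out-of-bounds positions are rejected
  far <- staticBead(100, 0)
  expect_error(renderVideo(far, imageShape = c(64, 64)), "bounds")
})

test_that("FRAP and persistence generators match their closed forms", {
  # plateau limit and full bleach at origin
  tr <- simulateFrapTrace(0.35, 0.05, noiseSd = 0,
                          tGrid = c(0, 10, 100, 1000))
  expect_identical(traceValues(tr)[1], 0)
  expect_equal(traceValues(tr)[4], 0.35, tolerance = 1e-6)
  # default grid is the every-20-s-to-140-s scheme
  expect_equal(traceTimes(simulateFrapTrace(0.2, 0.02)), seq(0, 140, 20))

  # persistence: fully stable, fully labile, default 2-min/1-h grid
  ps <- simulatePersistenceTrace(1, 100, tGrid = c(0, 50, 500))
  expect_equal(traceValues(ps), rep(1, 3))
  p0 <- simulatePersistenceTrace(0, 300, tGrid = c(0, 300, 3000))
  expect_equal(traceValues(p0), exp(-c(0, 300, 3000) / 300),
               tolerance = 1e-9)
  expect_true(all(diff(traceValues(p0)) < 0))
  expect_equal(traceTimes(simulatePersistenceTrace(0.5, 100)),
               seq(0, 3600, 120))

  expect_error(simulateFrapTrace(1.5, 0.1), "mobileFraction")
  expect_error(simulatePersistenceTrace(-0.1, 10), "stableFraction")
})

test_that("condensate fields carry faithful ground truth", {
  # pixel-counting oracle: one disk's mask area within 2% of pi r^2
  f1 <- simulateCondensateField(1, radii = 9, seed = 2)
  expect_equal(sum(f1$mask == 1), pi * 81, tolerance = 0.02)

  # empty field
  f0 <- simulateCondensateField(0, seed = 1)
  expect_identical(nrow(f0$truth), 0L)
  expect_identical(max(f0$mask), 0L)

  # touching pair flagged as a chain
  fc <- simulateCondensateField(0, radii = 8, touchingPair = TRUE, seed = 3)
  expect_identical(sum(fc$truth$chain), 2L)
  dd <- sqrt(diff(fc$truth$x_px)^2 + diff(fc$truth$y_px)^2)
  expect_equal(dd, 16, tolerance = 1e-9)

  # generators are deterministic in the seed
  g1 <- simulateCondensateField(5, seed = 9)
  g2 <- simulateCondensateField(5, seed = 9)
  expect_identical(g1$image, g2$image)
  expect_identical(g1$truth, g2$truth)
})
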