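test_that("bandpass removes background and suppresses noise", {
  # flat field maps to zero
  flat <- matrix(37, 32, 32)
  expect_true(all(bandpass(flat, 1, 7) == 0))

  # a rendered Gaussian spot keeps its maximum within 1 px
  rv <- renderVideo(staticBead(0.2, -0.1), peakSignal = 1000,
                    background = 20, readNoiseSd = 2,
                    imageShape = c(64, 64), seed = 3)
  img <- rv$stack@pixels[, , 1]
  before <- which(img == max(img), arr.ind = TRUE)[1, ]
  bp <- bandpass(img, 1, 7)
  after <- which(bp == max(bp), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(after - before)), 1)

  # pure white noise loses variance
  set.seed(4)
  noise <- matrix(rnorm(64^2), 64, 64)
  expect_lt(stats::var(as.vector(bandpass(noise, 1, 7))),
            stats::var(as.vector(noise)))

  expect_error(bandpass(flat, 3, 2), "noiseScale")
  expect_error(bandpass(flat, 1, 40), "smaller than the image")
})

test_that("single beads localize to better than a tenth of a pixel", {
  traj <- staticBead(0.033, -0.021)
  errs <- vapply(1:50, function(s) {
    rv <- renderVideo(traj, peakSignal = 2000, background = 10,
                      readNoiseSd = 2, imageShape = c(64, 64), seed = s)
    ft <- locateFeatures(rv$stack@pixels[, , 1], diameter = 7)
    expect_identical(nrow(ft), 1L)
    c(ft$x - rv$truth$x_px[1], ft$y - rv$truth$y_px[1])
  }, numeric(2))
  expect_lt(sqrt(mean(errs^2)), 0.1)
})

test_that("feature detection handles empty and multi-bead fields", {
  # empty field: zero detections
  set.seed(5)
  empty <- matrix(10 + rnorm(64^2, sd = 2), 64, 64)
  expect_identical(nrow(locateFeatures(empty, diameter = 7)), 0L)

  # two beads five diameters apart: exactly two detections, ordered
  traj <- staticBead(0, 0)
  d <- trajectories(traj)
  d <- rbind(d, d)
  d$x_um <- c(-1.75, 1.75)   # 35 px apart = 5 x 7 px
  traj@data <- d
  rv <- renderVideo(traj, peakSignal = 1500, background = 10,
                    readNoiseSd = 2, imageShape = c(96, 96), seed = 6)
  ft <- locateFeatures(rv$stack@pixels[, , 1], diameter = 7)
  expect_identical(nrow(ft), 2L)
  ft <- ft[order(ft$x), ]
  expect_equal(ft$x, sort(rv$truth$x_px), tolerance = 1e-3)
  expect_error(locateFeatures(empty, diameter = 6), "odd")
})

test_that("linking follows one bead and honours memory semantics", {
  # one bead, no gaps: one trajectory spanning all frames
  ft <- data.frame(frame = 0:9, x = 10 + (0:9) * 0.3, y = 20, mass = 1,
                   size = 1, ecc = 0)
  tr <- linkFeatures(ft, maxDisp = 5, memory = 0, dt = 0.1, pixelSize = 1)
  expect_identical(nTrajectories(tr), 1L)
  expect_identical(nrow(trajectories(tr)), 10L)
  expect_equal(trajectories(tr)$t_s, (0:9) * 0.1)

  # deleted middle detection: memory 1 bridges, memory 0 splits
  gap <- ft[ft$frame != 5, ]
  expect_identical(nTrajectories(linkFeatures(gap, 5, memory = 1,
                                              dt = 0.1, pixelSize = 1)), 1L)
  expect_identical(nTrajectories(linkFeatures(gap, 5, memory = 0,
                                              dt = 0.1, pixelSize = 1)), 2L)

  expect_error(linkFeatures(ft, maxDisp = 0), "maxDisp")
})

test_that("low-density linking recovers ground-truth identities", {
  m <- mediumModel("newtonian", eta = 0.1)
  traj <- gridTrajectories(m, nBeads = 16, nFrames = 200, spacing = 3,
                           seed = 9)
  d <- trajectories(traj)
  ft <- data.frame(frame = d$frame, x = d$x_um / 0.1, y = d$y_um / 0.1,
                   mass = 1, size = 1, ecc = 0)
  tr <- linkFeatures(ft, maxDisp = 5, memory = 3, dt = 0.015,
                     pixelSize = 0.1)
  got <- trajectories(tr)
  expect_identical(nTrajectories(tr), 16L)
  # every link must join positions of the same generative bead
  key <- paste(round(d$x_um, 9), round(d$y_um, 9))
  trueId <- d$trajectory_id[match(paste(round(got$x_um, 9),
                                        round(got$y_um, 9)), key)]
  agree <- vapply(split(trueId, got$trajectory_id),
                  function(v) length(unique(v)) == 1, logical(1))
  expect_gte(mean(agree), 0.99)
})

test_that("trajectory filtering drops short tracks and rim beads", {
  m <- mediumModel("newtonian", eta = 1)
  traj <- simulateTrajectories(m, nBeads = 6, nFrames = 50, seed = 2)
  # identity when every trajectory is long enough and no mask given
  expect_identical(trajectories(filterTrajectories(traj, minLength = 10)),
                   trajectories(traj))
  # boundary: a trajectory of length minLength - 1 is removed
  d <- trajectories(traj)
  d <- d[!(d$trajectory_id == 1 & d$frame >= 49), ]  # id 1 now 49 frames
  traj@data <- d
  kept <- filterTrajectories(traj, minLength = 50)
  expect_false(1 %in% trajectories(kept)$trajectory_id)
  expect_identical(nTrajectories(kept), 5L)

  # centre mask: rim beads removed under the default half-radius disc
  centre <- simulateTrajectories(m, nBeads = 3, nFrames = 50, seed = 3)
  rim <- simulateTrajectories(m, nBeads = 3, nFrames = 50, seed = 4)
  dr <- trajectories(rim)
  dr$x_um <- dr$x_um + 4          # condensate radius 5 um, rim at 4 um
  dr$trajectory_id <- dr$trajectory_id + 3
  both <- centre
  both@data <- rbind(trajectories(centre), dr)
  f <- filterTrajectories(both, minLength = 10,
                          centerMask = centerDisc(0, 0, 5))
  expect_equal(sort(unique(trajectories(f)$trajectory_id)), 1:3,
               ignore_attr = TRUE)
  expect_warning(
    filterTrajectories(both, minLength = 10,
                       centerMask = centerDisc(100, 100, 1)),
    "no trajectories")
})

test_that("render-track round trip reproduces the ground-truth MSD", {
  m <- mediumModel("newtonian", eta = 0.1)
  traj <- gridTrajectories(m, nBeads = 16, nFrames = 300, spacing = 3,
                           seed = 5)
  rv <- renderVideo(traj, pixelSize = 0.1, peakSignal = 800,
                    background = 10, readNoiseSd = 2,
                    imageShape = c(160, 160), seed = 2)
  ft <- locateFeatures(rv$stack, diameter = 7)
  tr <- filterTrajectories(
    linkFeatures(ft, maxDisp = 5, memory = 3, dt = 0.015, pixelSize = 0.1),
    minLength = 100)
  # no trajectory may contain two detections in one frame
  d <- trajectories(tr)
  expect_false(any(duplicated(d[, c("trajectory_id", "frame")])))

  lags <- (1:30) * 0.015
  mT <- ensembleMSD(tr, lags)
  mG <- ensembleMSD(traj, lags)
  sel <- msdLags(mT) >= 5 * 0.015
  expect_lt(max(abs(msdValues(mT)[sel] / msdValues(mG)[sel] - 1)), 0.1)
})

test_that("stationary beads expose the localization noise floor", {
  traj <- staticBead(0.07, 0.03, nFrames = 60)
  rv <- renderVideo(traj, peakSignal = 1500, background = 10,
                    readNoiseSd = 2, imageShape = c(64, 64), seed = 8)
  ft <- locateFeatures(rv$stack, diameter = 7)
  tr <- filterTrajectories(
    linkFeatures(ft, maxDisp = 2, memory = 0, dt = 0.015, pixelSize = 0.1),
    minLength = 50)
  est <- ensembleMSD(tr, c(1, 5, 20) * 0.015)
  off <- staticErrorOffset(est)
  # constant additive offset 4 sigma_loc^2: flat across lags, tiny
  expect_lt(diff(range(msdValues(est))) / off$offset, 0.5)
  expect_lt(off$sigmaLoc, 0.1 * 0.1)    # far below a tenth of a pixel (um)
})
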