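#' Simulate bead trajectories in a viscoelastic medium
#'
#' Brownian-dynamics generator whose sampled ensemble MSD matches
#' \code{\link{analyticMSD}} exactly at every lag >= \code{dt} (in
#' expectation).  Newtonian media use independent Gaussian increments of
#' per-axis variance \eqn{2 D\, dt}.  Maxwell media superimpose free
#' diffusion at the terminal diffusivity \eqn{D_0 = k_BT/(6\pi\eta_0 a)}
#' and independent per-frame Gaussian cage jitter of per-axis variance
#' \eqn{k_BT/(6\pi a G_0)}; because the Maxwell creep compliance is exactly
#' offset-plus-linear, this reproduces the Maxwell MSD at all lags without
#' a generalized-Langevin integrator.
#'
#' Defaults mirror stream-acquisition video particle tracking: 15 ms per
#' frame and 10,000 frames.
#'
#' @param model A \linkS4class{MediumModel}.
#' @param nBeads Number of beads (>= 1).
#' @param nFrames Frames per bead (>= 2).
#' @param dt Frame interval, s.
#' @param seed Integer seed; identical (model, config, seed) gives
#'   identical output.
#' @param dropletRadius Optional confining droplet radius, um; reflecting
#'   boundary about the droplet centre.  \code{NULL} disables confinement.
#' @param diffusionOff If TRUE, suppress the diffusive component of a
#'   Maxwell medium (the eta0 -> Inf pure-elastic limit); the MSD is then
#'   flat at the cage offset.
#' @param initialSpread Side of the square (um) over which unconfined
#'   beads start uniformly at random; 0 starts every bead at the origin
#'   (irrelevant for MSD, useful separation for rendering fixtures).
#' @return A \linkS4class{TrajectorySet} with positions in um.
#' @examples
#' m <- mediumModel("maxwell", eta0 = 31.8, tau = 4.6)
#' ts <- simulateTrajectories(m, nBeads = 5, nFrames = 100, seed = 1)
#' nTrajectories(ts)
#' @export
simulateTrajectories <- function(model, nBeads = 300, nFrames = 10000,
                                 dt = 0.015, seed = 1,
                                 dropletRadius = NULL,
                                 diffusionOff = FALSE,
                                 initialSpread = 0) {
  stopifnot(is(model, "MediumModel"))
  methods::validObject(model)
  if (nBeads < 1) stop("nBeads must be >= 1")
  if (nFrames < 2) stop("nFrames must be >= 2")
  if (dt <= 0) stop("dt must be > 0")
  kT <- .kB * model@temperature
  a <- model@beadRadius
  D0 <- diffusionCoefficient(model)               # m^2/s
  if (diffusionOff) {
    if (model@kind != "maxwell")
      stop("diffusionOff only applies to maxwell media")
    D0 <- 0
  }
  sdDiff <- sqrt(2 * D0 * dt) * 1e6               # um, per axis per frame
  sdCage <- if (model@kind == "maxwell") {
    sqrt(kT / (6 * pi * a * plateauModulus(model))) * 1e6
  } else 0
  if (!is.null(dropletRadius)) {
    if (dropletRadius <= 0) stop("dropletRadius must be > 0")
    if (3 * (sdDiff + sdCage) >= dropletRadius)
      stop("dropletRadius smaller than the expected per-frame step")
  }
  set.seed(as.integer(seed))
  nb <- as.integer(nBeads); nf <- as.integer(nFrames)

  if (is.null(dropletRadius)) {
    x0 <- if (initialSpread > 0)
      stats::runif(nb, -initialSpread / 2, initialSpread / 2) else
      rep(0, nb)
    y0 <- if (initialSpread > 0)
      stats::runif(nb, -initialSpread / 2, initialSpread / 2) else
      rep(0, nb)
    cx <- apply(matrix(stats::rnorm(nf * nb, sd = sdDiff), nf, nb), 2, cumsum)
    cy <- apply(matrix(stats::rnorm(nf * nb, sd = sdDiff), nf, nb), 2, cumsum)
    cx <- sweep(cx, 2, x0, `+`)
    cy <- sweep(cy, 2, y0, `+`)
    if (sdCage > 0) {
      cx <- cx + matrix(stats::rnorm(nf * nb, sd = sdCage), nf, nb)
      cy <- cy + matrix(stats::rnorm(nf * nb, sd = sdCage), nf, nb)
    }
  } else {
    # reflecting confinement acts on the diffusive path; cage jitter rides
    # on top (its amplitude is checked against the droplet size above)
    r0 <- dropletRadius * sqrt(stats::runif(nb))
    th0 <- stats::runif(nb, 0, 2 * pi)
    px <- r0 * cos(th0); py <- r0 * sin(th0)
    cx <- matrix(0, nf, nb); cy <- matrix(0, nf, nb)
    for (f in seq_len(nf)) {
      px <- px + stats::rnorm(nb, sd = sdDiff)
      py <- py + stats::rnorm(nb, sd = sdDiff)
      r <- sqrt(px^2 + py^2)
      out <- r > dropletRadius
      if (any(out)) {
        fold <- (2 * dropletRadius - r[out]) / r[out]
        px[out] <- px[out] * fold
        py[out] <- py[out] * fold
      }
      cx[f, ] <- px; cy[f, ] <- py
    }
    if (sdCage > 0) {
      cx <- cx + matrix(stats::rnorm(nf * nb, sd = sdCage), nf, nb)
      cy <- cy + matrix(stats::rnorm(nf * nb, sd = sdCage), nf, nb)
    }
  }

  frames <- rep(seq_len(nf) - 1L, nb)
  d <- data.frame(
    trajectory_id = rep(seq_len(nb), each = nf),
    frame = frames,
    t_s = frames * dt,
    x_um = as.vector(cx),
    y_um = as.vector(cy))
  methods::new("TrajectorySet", data = d, dt = dt, pixelSize = NA_real_,
               beadRadius = a, temperature = model@temperature,
               seed = as.numeric(seed))
}

#' @rdname vptRheo-accessors
setMethod("trajectories", "TrajectorySet", function(x) x@data)
#' @rdname vptRheo-accessors
setMethod("nTrajectories", "TrajectorySet",
          function(x) length(unique(x@data$trajectory_id)))
#' @rdname vptRheo-accessors
setMethod("frameInterval", "TrajectorySet", function(x) x@dt)
#' @rdname vptRheo-accessors
setMethod("pixelSize", "TrajectorySet", function(x) x@pixelSize)
#' @rdname vptRheo-accessors
setMethod("beadRadius", "TrajectorySet", function(x) x@beadRadius)
#' @rdname vptRheo-accessors
setMethod("temperature", "TrajectorySet", function(x) x@temperature)

setMethod("show", "TrajectorySet", function(object) {
  d <- object@data
  cat(sprintf(
    "TrajectorySet: %d trajectories, %d points, dt = %g s\n",
    length(unique(d$trajectory_id)), nrow(d), object@dt))
  cat(sprintf("  bead radius %g nm, T = %g K\n",
              object@beadRadius * 1e9, object@temperature))
})

# additive Gaussian-spot rendering of one frame (expected photons)
.renderFrame <- function(nx, ny, x, y, psfSigma, peakSignal, background) {
  img <- matrix(background, ny, nx)
  w <- ceiling(4 * psfSigma)
  for (i in seq_along(x)) {
    cx <- x[i]; cy <- y[i]
    ix <- max(1, floor(cx) - w):min(nx, ceiling(cx) + w)
    iy <- max(1, floor(cy) - w):min(ny, ceiling(cy) + w)
    if (!length(ix) || !length(iy)) next
    gx <- exp(-((ix - cx)^2) / (2 * psfSigma^2))
    gy <- exp(-((iy - cy)^2) / (2 * psfSigma^2))
    img[iy, ix] <- img[iy, ix] + peakSignal * outer(gy, gx)
  }
  img
}

#' Render a trajectory set as a noisy fluorescence video
#'
#' Beads are drawn as 2D Gaussian spots of width \code{psfSigma}; Poisson
#' photon noise and Gaussian read noise are applied per pixel.  Ground
#' truth pixel positions are retained alongside so localization accuracy
#' can be scored downstream.
#'
#' Coordinate convention: pixel centres at integer coordinates, origin at
#' top-left, x = column, y = row.  Positions in um are mapped to pixels as
#' \code{x_px = x_um/pixelSize + origin[1]}.
#'
#' @param traj A \linkS4class{TrajectorySet}.
#' @param pixelSize um per pixel.
#' @param psfSigma PSF standard deviation, px.
#' @param peakSignal Expected photons at a spot peak (0 gives an empty
#'   field).
#' @param background Expected background photons per pixel.
#' @param readNoiseSd Gaussian read noise, counts.
#' @param imageShape c(rows, cols) of each frame.
#' @param origin Pixel coordinates (x, y) that um position (0, 0) maps to;
#'   default is the image centre.
#' @param seed Seed for the noise draws.
#' @return List with \code{stack} (an \linkS4class{ImageStack}) and
#'   \code{truth} (data.frame trajectory_id, frame, x_px, y_px).
#' @export
renderVideo <- function(traj, pixelSize = 0.1, psfSigma = 1.3,
                        peakSignal = 500, background = 10,
                        readNoiseSd = 2, imageShape = c(128, 128),
                        origin = NULL, seed = 1) {
  stopifnot(is(traj, "TrajectorySet"))
  if (pixelSize <= 0) stop("pixelSize must be > 0")
  if (psfSigma <= 0) stop("psfSigma must be > 0")
  if (peakSignal < 0) stop("peakSignal must be >= 0")
  d <- traj@data
  ny <- imageShape[1]; nx <- imageShape[2]
  if (is.null(origin)) origin <- c((nx + 1) / 2, (ny + 1) / 2)
  xpx <- d$x_um / pixelSize + origin[1]
  ypx <- d$y_um / pixelSize + origin[2]
  pad <- 3 * psfSigma
  if (any(xpx < 1 - pad | xpx > nx + pad | ypx < 1 - pad | ypx > ny + pad))
    stop("trajectory positions fall outside the image bounds")
  set.seed(as.integer(seed))
  frames <- sort(unique(d$frame))
  px <- array(0, dim = c(ny, nx, length(frames)))
  for (fi in seq_along(frames)) {
    sel <- d$frame == frames[fi]
    expected <- .renderFrame(nx, ny, xpx[sel], ypx[sel],
                             psfSigma, peakSignal, background)
    obs <- stats::rpois(length(expected), expected) +
      stats::rnorm(length(expected), sd = readNoiseSd)
    px[, , fi] <- pmax(matrix(obs, ny, nx), 0)
  }
  truth <- data.frame(trajectory_id = d$trajectory_id, frame = d$frame,
                      x_px = xpx, y_px = ypx)
  list(stack = methods::new("ImageStack", pixels = px, dt = traj@dt,
                            pixelSize = pixelSize),
       truth = truth)
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageStack: %d x %d px, %d frames, dt = %g s, %g um/px\n",
              d[1], d[2], d[3], object@dt, object@pixelSize))
})

#' Construct an intensity trace
#'
#' @param t Time, s, strictly increasing.
#' @param value Intensity values.
#' @param role "bleached", "reference", "background" or "normalized".
#' @param bleachIndex Index of the first post-bleach point (optional).
#' @return An \linkS4class{IntensityTrace}.
#' @export
intensityTrace <- function(t, value, role = "bleached",
                           bleachIndex = NA_real_) {
  methods::new("IntensityTrace", t = as.numeric(t),
               value = as.numeric(value), role = role,
               bleachIndex = as.numeric(bleachIndex))
}

#' @rdname vptRheo-accessors
setMethod("traceTimes", "IntensityTrace", function(x) x@t)
#' @rdname vptRheo-accessors
setMethod("traceValues", "IntensityTrace", function(x) x@value)

setMethod("show", "IntensityTrace", function(object) {
  cat(sprintf("IntensityTrace (%s): %d points, t = %g..%g s\n",
              object@role, length(object@t),
              min(object@t), max(object@t)))
})

#' Simulate a normalized one-phase FRAP recovery trace
#'
#' \deqn{I(t) = m (1 - e^{-k t}) + \epsilon,\qquad \epsilon \sim
#'   N(0, \sigma^2)} on the post-bleach clock, so \eqn{I(0) = 0}
#' (noise-free) and \eqn{I \to m} as \eqn{t \to \infty}.  The default time
#' grid samples every 20 s until 140 s, the in vivo centrosome FRAP
#' scheme.
#'
#' @param mobileFraction Recovery plateau in [0, 1].
#' @param k Recovery rate, 1/s.
#' @param noiseSd Gaussian noise sd (unitless).
#' @param tGrid Post-bleach sample times, s.
#' @param seed Optional seed for the noise draws.
#' @return An \linkS4class{IntensityTrace} with role "normalized" and
#'   \code{bleachIndex = 1}.
#' @export
simulateFrapTrace <- function(mobileFraction, k, noiseSd = 0,
                              tGrid = seq(0, 140, by = 20), seed = NULL) {
  if (mobileFraction < 0 || mobileFraction > 1)
    stop("mobileFraction must lie in [0, 1]")
  if (k <= 0) stop("k must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- mobileFraction * (1 - exp(-k * tGrid))
  if (noiseSd > 0) v <- v + stats::rnorm(length(tGrid), sd = noiseSd)
  intensityTrace(tGrid, pmin(1.2, pmax(-0.2, v)), role = "normalized",
                 bleachIndex = 1)
}

#' Simulate a normalized persistence (extrusion/dilution) trace
#'
#' Biphasic decay: a rapid initial decline to a stable plateau,
#' \deqn{I(t) = s + (1 - s) e^{-t/\tau_d} + \epsilon,}
#' starting at 1 (noise-free).  \code{stableFraction = 0} gives a pure
#' exponential loss; \code{stableFraction = 1} a fully stable scaffold.
#' The default grid images every 2 min for 1 h.
#'
#' @param stableFraction Plateau fraction in [0, 1].
#' @param tauDecay Decay time of the labile pool, s.
#' @param noiseSd Gaussian noise sd.
#' @param tGrid Sample times, s.
#' @param seed Optional seed.
#' @return An \linkS4class{IntensityTrace} with role "normalized".
#' @export
simulatePersistenceTrace <- function(stableFraction, tauDecay,
                                     noiseSd = 0,
                                     tGrid = seq(0, 3600, by = 120),
                                     seed = NULL) {
  if (stableFraction < 0 || stableFraction > 1)
    stop("stableFraction must lie in [0, 1]")
  if (tauDecay <= 0) stop("tauDecay must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- stableFraction + (1 - stableFraction) * exp(-tGrid / tauDecay)
  if (noiseSd > 0) v <- v + stats::rnorm(length(tGrid), sd = noiseSd)
  intensityTrace(tGrid, pmin(1.2, pmax(-0.2, v)), role = "normalized")
}

#' Simulate a field of condensates with ground truth
#'
#' Disks with PSF-blurred edges on a noisy background, plus a ground-truth
#' table (centre, radius, injected integrated intensity above background)
#' and the noiseless label mask.  Optionally appends a pair of touching
#' equal disks flagged as a chain, the fixture for watershed splitting.
#'
#' @param n Number of isolated disks (>= 0).
#' @param radii Disk radii, px (recycled to length \code{n}).
#' @param intensities Disk intensities above background, a.u. (recycled).
#' @param imageShape c(rows, cols).
#' @param psfSigma Gaussian blur sd, px.
#' @param background Background level, a.u.
#' @param readNoiseSd Gaussian noise sd, a.u.
#' @param touchingPair If TRUE, add two touching disks (truth column
#'   \code{chain} marks them).
#' @param seed Seed for placement and noise.
#' @return List with \code{image} (matrix), \code{truth} (data.frame id,
#'   x_px, y_px, radius_px, intensity, total_intensity, chain) and
#'   \code{mask} (noiseless integer label matrix).
#' @export
simulateCondensateField <- function(n, radii = 8, intensities = 100,
                                    imageShape = c(256, 256),
                                    psfSigma = 1, background = 10,
                                    readNoiseSd = 2,
                                    touchingPair = FALSE, seed = 1) {
  if (n < 0) stop("n must be >= 0")
  set.seed(as.integer(seed))
  ny <- imageShape[1]; nx <- imageShape[2]
  radii <- rep_len(radii, max(n, 1))
  intensities <- rep_len(intensities, max(n, 1))
  centers <- matrix(numeric(0), 0, 2)
  rads <- numeric(0); ints <- numeric(0); chain <- logical(0)
  margin <- max(radii) + 4 * psfSigma + 2
  if (n > 0) {
    tries <- 0
    while (nrow(centers) < n && tries < 10000) {
      tries <- tries + 1
      cand <- c(stats::runif(1, margin, nx - margin),
                stats::runif(1, margin, ny - margin))
      r <- radii[nrow(centers) + 1]
      ok <- TRUE
      if (nrow(centers)) {
        dd <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
        ok <- all(dd > r + rads + 4 * psfSigma + 2)
      }
      if (ok) {
        centers <- rbind(centers, cand)
        rads <- c(rads, r)
        ints <- c(ints, intensities[length(ints) + 1])
        chain <- c(chain, FALSE)
      }
    }
    if (nrow(centers) < n) stop("could not place all disks; reduce n or radii")
  }
  if (touchingPair) {
    r <- radii[1]
    cy <- ny / 2
    cx <- margin + r
    # keep the pair clear of the isolated disks
    while (nrow(centers) &&
           any(sqrt((centers[, 1] - (cx + r))^2 + (centers[, 2] - cy)^2) <
               2 * r + max(rads) + 4 * psfSigma + 2) && cx < nx - margin) {
      cx <- cx + 1
    }
    centers <- rbind(centers, c(cx, cy), c(cx + 2 * r, cy))
    rads <- c(rads, r, r)
    ints <- c(ints, intensities[1], intensities[1])
    chain <- c(chain, TRUE, TRUE)
  }
  clean <- matrix(0, ny, nx)
  mask <- matrix(0L, ny, nx)
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), nx), ny, nx)
  for (i in seq_len(nrow(centers))) {
    inside <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= rads[i]^2
    clean[inside] <- clean[inside] + ints[i]
    mask[inside] <- i
  }
  blurred <- if (psfSigma > 0) {
    as.matrix(EBImage::gblur(EBImage::Image(clean), sigma = psfSigma))
  } else clean
  img <- blurred + background
  if (readNoiseSd > 0)
    img <- img + matrix(stats::rnorm(ny * nx, sd = readNoiseSd), ny, nx)
  truth <- if (nrow(centers)) {
    data.frame(id = seq_len(nrow(centers)), x_px = centers[, 1],
               y_px = centers[, 2], radius_px = rads, intensity = ints,
               total_intensity = ints * vapply(seq_len(nrow(centers)),
                 function(i) sum(mask == i), numeric(1)),
               chain = chain)
  } else {
    data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
               radius_px = numeric(0), intensity = numeric(0),
               total_intensity = numeric(0), chain = logical(0))
  }
  list(image = pmax(img, 0), truth = truth, mask = mask)
}
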