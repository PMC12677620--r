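#' Crocker-Grier bandpass filter
#'
#' Suppresses pixel noise with a Gaussian of width \code{noiseScale} and
#' removes slowly varying background with a boxcar of width
#' \code{featureScale}; their difference is clipped at zero.  Standard
#' preprocessing before spot detection.
#'
#' @param image 2D numeric matrix.
#' @param noiseScale Gaussian sd, px; must satisfy
#'   \code{0 < noiseScale < featureScale}.
#' @param featureScale Boxcar width, px (roughly the feature diameter).
#' @return Non-negative filtered matrix of the same size.
#' @export
bandpass <- function(image, noiseScale = 1, featureScale = 7) {
  if (!is.matrix(image)) image <- as.matrix(image)
  if (noiseScale <= 0 || noiseScale >= featureScale)
    stop("need 0 < noiseScale < featureScale")
  if (featureScale >= min(dim(image)))
    stop("featureScale must be smaller than the image")
  half <- ceiling(4 * noiseScale)
  g <- stats::dnorm(-half:half, sd = noiseScale)
  g <- g / sum(g)
  low <- .sepConv(image, g)
  w <- 2 * floor(featureScale / 2) + 1
  bg <- .sepConv(image, rep(1 / w, w))
  pmax(low - bg, 0)
}

# separable convolution with replicate padding, applied along both axes
.sepConv <- function(m, kernel) {
  half <- (length(kernel) - 1) / 2
  convRows <- function(x) {
    n <- nrow(x)
    padded <- rbind(x[rep(1, half), , drop = FALSE], x,
                    x[rep(n, half), , drop = FALSE])
    out <- matrix(0, n, ncol(x))
    for (k in seq_along(kernel)) {
      out <- out + kernel[k] * padded[(k - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(convRows(t(convRows(m))))
}

# iterative intensity-weighted centroid refinement within a disc mask
.refineCentroid <- function(bp, x0, y0, radius, maxIter = 10) {
  ny <- nrow(bp); nx <- ncol(bp)
  off <- seq(-radius, radius)
  disc <- outer(off, off, function(dy, dx) dx^2 + dy^2 <= radius^2)
  dxm <- matrix(rep(off, each = length(off)), length(off))  # column offsets
  dym <- matrix(rep(off, length(off)), length(off))         # row offsets
  cx <- x0; cy <- y0
  for (it in seq_len(maxIter)) {
    ix <- round(cx); iy <- round(cy)
    if (ix - radius < 1 || ix + radius > nx ||
        iy - radius < 1 || iy + radius > ny) break
    win <- bp[(iy - radius):(iy + radius), (ix - radius):(ix + radius)]
    w <- win * disc
    m <- sum(w)
    if (m <= 0) break
    sx <- sum(w * dxm) / m
    sy <- sum(w * dym) / m
    cx <- ix + sx; cy <- iy + sy
    if (abs(sx) < 0.5 && abs(sy) < 0.5 && it > 1) break
  }
  ix <- round(cx); iy <- round(cy)
  if (ix - radius < 1 || ix + radius > nx ||
      iy - radius < 1 || iy + radius > ny)
    return(NULL)
  win <- bp[(iy - radius):(iy + radius), (ix - radius):(ix + radius)]
  w <- win * disc
  m <- sum(w)
  if (m <= 0) return(NULL)
  r2 <- sum(w * (dxm^2 + dym^2)) / m
  mxx <- sum(w * dxm^2) / m; myy <- sum(w * dym^2) / m
  mxy <- sum(w * dxm * dym) / m
  ecc <- sqrt((mxx - myy)^2 + 4 * mxy^2) / (mxx + myy + 1e-12)
  c(x = ix + sum(w * dxm) / m, y = iy + sum(w * dym) / m,
    mass = m, size = sqrt(r2), ecc = ecc)
}

#' @describeIn locateFeatures Detect bright spots in one frame.  Local
#'   maxima of the bandpassed image above the \code{percentileThreshold}
#'   quantile are refined to sub-pixel centroids by iterative
#'   intensity-weighted averaging over a disc of radius
#'   \code{(diameter-1)/2} (at most 10 iterations); detections with mass
#'   below \code{minMass} are discarded.
#'
#' @param diameter Odd feature diameter, px (>= 3).
#' @param minMass Minimum integrated (bandpassed) intensity; the main
#'   guard against shot-noise maxima.  The default rejects candidates
#'   whose mass is consistent with background fluctuations (20 times the
#'   robust scale of the bandpassed image per disc).
#' @param percentileThreshold Quantile of the positive bandpassed pixels
#'   below which pixels cannot seed a feature.
#' @param noiseScale Bandpass noise scale passed to \code{\link{bandpass}}.
#' @return data.frame with columns \code{x}, \code{y} (px, sub-pixel),
#'   \code{mass}, \code{size} (radius of gyration, px), \code{ecc}.
#' @export
setMethod("locateFeatures", "matrix",
function(image, diameter = 7, minMass = NULL, percentileThreshold = 0.9,
         noiseScale = 1) {
  if (diameter %% 2 != 1 || diameter < 3)
    stop("diameter must be odd and >= 3")
  bp <- bandpass(image, noiseScale = noiseScale, featureScale = diameter)
  radius <- (diameter - 1) / 2
  posPix <- bp[bp > 0]
  if (is.null(minMass)) {
    # background fluctuation scale after bandpass; a genuine spot
    # integrates far above this over its disc
    noise <- stats::median(posPix)
    minMass <- 20 * noise * pi * radius^2 / 2
  }
  empty <- data.frame(x = numeric(0), y = numeric(0), mass = numeric(0),
                      size = numeric(0), ecc = numeric(0))
  if (!length(posPix)) return(empty)
  thr <- stats::quantile(posPix, percentileThreshold)
  if (thr <= 0) thr <- .Machine$double.eps
  # local maxima within a disc neighbourhood via grey dilation
  brush <- EBImage::makeBrush(diameter, shape = "disc")
  dil <- as.matrix(EBImage::dilate(EBImage::Image(bp), brush))
  cand <- which(bp >= dil - 1e-12 & bp > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  taken <- matrix(FALSE, nrow(bp), ncol(bp))
  ord <- order(bp[cand], decreasing = TRUE)
  acc <- matrix(NA_real_, length(ord), 5)
  n <- 0L
  for (i in ord) {
    y0 <- cand[i, 1]; x0 <- cand[i, 2]
    if (taken[y0, x0]) next
    # suppress further candidates within one radius regardless of outcome
    ys <- max(1, y0 - radius):min(nrow(bp), y0 + radius)
    xs <- max(1, x0 - radius):min(ncol(bp), x0 + radius)
    taken[ys, xs] <- TRUE
    f <- .refineCentroid(bp, x0, y0, radius)
    if (is.null(f) || f["mass"] < minMass) next
    n <- n + 1L
    acc[n, ] <- f
  }
  if (!n) return(empty)
  out <- as.data.frame(acc[seq_len(n), , drop = FALSE])
  names(out) <- c("x", "y", "mass", "size", "ecc")
  # drop near-duplicate refinements closer than one radius
  if (nrow(out) > 1) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out) - 1)) {
      if (!keep[i]) next
      d2 <- (out$x[-(1:i)] - out$x[i])^2 + (out$y[-(1:i)] - out$y[i])^2
      dup <- which(d2 < radius^2) + i
      keep[dup[out$mass[dup] <= out$mass[i]]] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
})

#' @describeIn locateFeatures Detect features in every frame of a stack;
#'   adds a \code{frame} column (0-based, matching trajectory frames).
#' @export
setMethod("locateFeatures", "ImageStack", function(image, ...) {
  nf <- dim(image@pixels)[3]
  res <- vector("list", nf)
  for (f in seq_len(nf)) {
    ft <- locateFeatures(image@pixels[, , f], ...)
    if (nrow(ft)) ft$frame <- f - 1L else ft$frame <- integer(0)
    res[[f]] <- ft
  }
  do.call(rbind, res)
})

#' Link features into trajectories
#'
#' Frame-to-frame assignment in the Crocker-Grier spirit: candidate pairs
#' within \code{maxDisp} are assigned greedily in order of increasing
#' displacement (a near-optimal proxy for minimising total squared
#' displacement at tracking densities where steps are small compared with
#' spacing).  A track missing a detection stays alive for up to
#' \code{memory} frames and may bridge the gap; each detection joins at
#' most one trajectory, and features contested beyond resolution start
#' new trajectories.
#'
#' @param features data.frame from \code{\link{locateFeatures}} with
#'   columns \code{frame}, \code{x}, \code{y}.
#' @param maxDisp Maximum displacement per frame step, px.
#' @param memory Frames a lost track may survive without a detection.
#' @param dt Frame interval, s.
#' @param pixelSize um per px used to convert output positions.
#' @param beadRadius,temperature Metadata carried into the output.
#' @return A \linkS4class{TrajectorySet} (positions in um).
#' @export
linkFeatures <- function(features, maxDisp = 5, memory = 3, dt = 0.015,
                         pixelSize = 0.1, beadRadius = 50e-9,
                         temperature = 303.15) {
  if (maxDisp <= 0) stop("maxDisp must be > 0")
  if (memory < 0) stop("memory must be >= 0")
  need <- c("frame", "x", "y")
  if (!all(need %in% names(features)))
    stop("features must have columns frame, x, y")
  if (!nrow(features))
    stop("no features to link")
  features <- features[order(features$frame), , drop = FALSE]
  frames <- sort(unique(features$frame))
  # active track state
  trackX <- numeric(0); trackY <- numeric(0)
  trackLast <- integer(0); trackId <- integer(0)
  nextId <- 1L
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    sel <- features$frame == f
    fx <- features$x[sel]; fy <- features$y[sel]
    nFeat <- length(fx)
    assigned <- rep(NA_integer_, nFeat)
    if (length(trackId) && nFeat) {
      alive <- which(f - trackLast <= memory + 1L)
      if (length(alive)) {
        dx <- outer(trackX[alive], fx, `-`)
        dy <- outer(trackY[alive], fy, `-`)
        d2 <- dx * dx + dy * dy
        cand <- which(d2 <= maxDisp^2, arr.ind = TRUE)
        if (nrow(cand)) {
          ord <- order(d2[cand])
          usedTrack <- rep(FALSE, length(alive))
          for (ci in ord) {
            ti <- cand[ci, 1]; fj <- cand[ci, 2]
            if (usedTrack[ti] || !is.na(assigned[fj])) next
            usedTrack[ti] <- TRUE
            assigned[fj] <- alive[ti]
          }
        }
      }
    }
    newRows <- data.frame(trajectory_id = integer(nFeat), frame = f,
                          t_s = f * dt, x_um = fx * pixelSize,
                          y_um = fy * pixelSize)
    for (j in seq_len(nFeat)) {
      if (is.na(assigned[j])) {
        trackX <- c(trackX, fx[j]); trackY <- c(trackY, fy[j])
        trackLast <- c(trackLast, f); trackId <- c(trackId, nextId)
        newRows$trajectory_id[j] <- nextId
        nextId <- nextId + 1L
      } else {
        ti <- assigned[j]
        trackX[ti] <- fx[j]; trackY[ti] <- fy[j]; trackLast[ti] <- f
        newRows$trajectory_id[j] <- trackId[ti]
      }
    }
    rows[[fi]] <- newRows
  }
  d <- do.call(rbind, rows)
  d <- d[order(d$trajectory_id, d$frame), , drop = FALSE]
  rownames(d) <- NULL
  methods::new("TrajectorySet", data = d, dt = dt, pixelSize = pixelSize,
               beadRadius = beadRadius, temperature = temperature,
               seed = NA_real_)
}

#' Filter trajectories by length and position
#'
#' Drops trajectories observed for fewer than \code{minLength} frames.
#' When \code{centerMask} is given, additionally keeps only trajectories
#' whose mean position lies inside the mask; this implements the
#' condensate-centre restriction that minimises confinement effects (the
#' conventional default mask is a disc of half the condensate radius
#' about its centroid, see \code{\link{centerDisc}}).
#'
#' @param traj A \linkS4class{TrajectorySet}.
#' @param minLength Minimum number of observed frames (>= 2).
#' @param centerMask Either \code{NULL} or a list with \code{x}, \code{y}
#'   and \code{radius} in um.
#' @return The filtered \linkS4class{TrajectorySet}; empty results are
#'   allowed (with a warning).
#' @export
filterTrajectories <- function(traj, minLength = 100, centerMask = NULL) {
  stopifnot(is(traj, "TrajectorySet"))
  if (minLength < 2) stop("minLength must be >= 2")
  d <- traj@data
  len <- table(d$trajectory_id)
  keepIds <- as.numeric(names(len)[len >= minLength])
  if (!is.null(centerMask)) {
    if (!all(c("x", "y", "radius") %in% names(centerMask)))
      stop("centerMask must have x, y and radius")
    mx <- tapply(d$x_um, d$trajectory_id, mean)
    my <- tapply(d$y_um, d$trajectory_id, mean)
    inside <- (mx - centerMask$x)^2 + (my - centerMask$y)^2 <=
      centerMask$radius^2
    keepIds <- intersect(keepIds, as.numeric(names(mx)[inside]))
  }
  out <- d[d$trajectory_id %in% keepIds, , drop = FALSE]
  if (!nrow(out)) warning("no trajectories left after filtering")
  rownames(out) <- NULL
  traj@data <- out
  traj
}

#' Default condensate-centre mask
#'
#' A disc of half the condensate radius about its centroid, the
#' conventional region within which bead trajectories are considered free
#' of boundary effects.
#'
#' @param x,y Condensate centroid, um.
#' @param condensateRadius Condensate radius, um.
#' @return A list usable as \code{centerMask} in
#'   \code{\link{filterTrajectories}}.
#' @export
centerDisc <- function(x, y, condensateRadius) {
  list(x = x, y = y, radius = condensateRadius / 2)
}

#' Localization-noise MSD offset
#'
#' Static localization error adds a constant \eqn{4\sigma_{loc}^2} to the
#' 2D MSD.  Estimated from a stationary-bead fixture as the mean MSD over
#' the supplied lags; used to report (and optionally subtract) the noise
#' floor before GSER.
#'
#' @param curve MSD of stationary beads (\linkS4class{MSDCurve}).
#' @return List with \code{offset} (um^2, the mean MSD level) and
#'   \code{sigmaLoc} (um, \eqn{\sqrt{offset/4}}).
#' @export
staticErrorOffset <- function(curve) {
  stopifnot(is(curve, "MSDCurve"))
  off <- mean(curve@msd)
  list(offset = off, sigmaLoc = sqrt(max(off, 0) / 4))
}
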