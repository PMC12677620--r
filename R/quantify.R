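#' Segment condensates in a fluorescence image
#'
#' Threshold-based segmentation in the semi-automated style of particle
#' analysis: a 3 px median filter, an Otsu (or fixed) threshold, optional
#' distance-transform watershed to split chains of touching condensates,
#' and removal of objects below \code{minSize} pixels.
#'
#' @param image 2D numeric matrix.
#' @param thresholdMethod "otsu" or "fixed".
#' @param threshold Intensity threshold when \code{thresholdMethod =
#'   "fixed"}.
#' @param watershed Split touching objects with a distance-transform
#'   watershed.
#' @param minSize Minimum object size, px.
#' @param medianSize Median prefilter size, px (odd; 0 disables).
#' @return Integer label matrix (0 = background) with attribute
#'   \code{provenance} recording the method, threshold, watershed flag
#'   and minimum size.
#' @export
segmentCondensates <- function(image, thresholdMethod = c("otsu", "fixed"),
                               threshold = NULL, watershed = FALSE,
                               minSize = 9, medianSize = 3) {
  thresholdMethod <- match.arg(thresholdMethod)
  if (!is.matrix(image)) image <- as.matrix(image)
  rng <- range(image)
  if (thresholdMethod == "otsu" && rng[1] == rng[2])
    stop("constant image: Otsu threshold undefined")
  norm <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
          else image * 0
  if (medianSize >= 3) {
    norm <- as.matrix(EBImage::medianFilter(EBImage::Image(norm),
                                            size = floor(medianSize / 2)))
  }
  thr <- if (thresholdMethod == "otsu") {
    # Otsu splits pure noise in half; insist foreground also clears the
    # background level by 3 robust sd so an empty field yields no objects
    floorThr <- stats::median(norm) + 3 * stats::mad(norm)
    max(EBImage::otsu(EBImage::Image(norm), range = c(0, 1)), floorThr)
  } else {
    if (is.null(threshold)) stop("fixed thresholding needs a threshold")
    if (rng[2] > rng[1]) (threshold - rng[1]) / (rng[2] - rng[1])
    else threshold
  }
  mask <- norm > thr
  labels <- if (watershed) {
    dm <- EBImage::distmap(EBImage::Image(mask))
    as.matrix(EBImage::watershed(dm))
  } else {
    as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  }
  # drop small objects, relabel contiguously
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= minSize)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0
  out[pos] <- relab[labels[pos]]
  attr(out, "provenance") <- list(threshold_method = thresholdMethod,
                                  threshold = as.numeric(thr),
                                  watershed = watershed, min_size = minSize)
  out
}

#' Per-object intensity and geometry statistics
#'
#' Area, raw mean intensity, integrated density (raw pixel sum, so that
#' integrated density = mean x pixel count), background-subtracted
#' integrated density (frame background = median of non-object pixels)
#' and centroid for every labelled object, plus a summary (mean area with
#' its 95 percent confidence interval across objects).
#'
#' @param image 2D numeric matrix.
#' @param labels Integer label matrix from
#'   \code{\link{segmentCondensates}}.
#' @param pixelSize um per px; areas come out in um^2 and centroids in um.
#' @return List with \code{objects} (data.frame: label, n_px, area_um2,
#'   mean_intensity, integrated_density, integrated_density_bgsub,
#'   x_um, y_um) and \code{summary} (mean area, 95\% CI, object count,
#'   background level).
#' @export
objectStats <- function(image, labels, pixelSize = 1) {
  if (!all(dim(image) == dim(labels))) stop("labels must match image shape")
  ids <- sort(unique(labels[labels > 0]))
  bg <- if (any(labels == 0)) stats::median(image[labels == 0]) else 0
  xs <- matrix(rep(seq_len(ncol(image)), each = nrow(image)), nrow(image))
  ys <- matrix(rep(seq_len(nrow(image)), ncol(image)), nrow(image))
  rows <- lapply(ids, function(i) {
    sel <- labels == i
    n <- sum(sel)
    s <- sum(image[sel])
    data.frame(label = i, n_px = n, area_um2 = n * pixelSize^2,
               mean_intensity = s / n, integrated_density = s,
               integrated_density_bgsub = s - bg * n,
               x_um = mean(xs[sel]) * pixelSize,
               y_um = mean(ys[sel]) * pixelSize)
  })
  objects <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), n_px = integer(0), area_um2 = numeric(0),
               mean_intensity = numeric(0), integrated_density = numeric(0),
               integrated_density_bgsub = numeric(0), x_um = numeric(0),
               y_um = numeric(0))
  n <- nrow(objects)
  ciHalf <- if (n > 1) {
    stats::qt(0.975, n - 1) * stats::sd(objects$area_um2) / sqrt(n)
  } else NA_real_
  list(objects = objects,
       summary = list(n_objects = n,
                      mean_area_um2 = if (n) mean(objects$area_um2)
                                      else NA_real_,
                      area_ci95 = ciHalf, background = bg))
}

#' Partition coefficient of condensates
#'
#' Per-object ratio of the mean intensity inside the object to the mean
#' intensity of the dilute phase, where the dilute phase is the
#' background after excluding a \code{rim}-pixel dilated ring around
#' every object (to avoid PSF bleed).
#'
#' @param image 2D numeric matrix.
#' @param labels Integer label matrix.
#' @param rim Rim exclusion width, px.
#' @return List with \code{objects} (data.frame label, ratio),
#'   \code{diluteMean} and \code{summary} (mean ratio).
#' @export
partitionCoefficient <- function(image, labels, rim = 2) {
  if (!all(dim(image) == dim(labels))) stop("labels must match image shape")
  mask <- labels > 0
  dilute <- if (rim > 0) {
    brush <- EBImage::makeBrush(2 * rim + 1, shape = "disc")
    grown <- as.matrix(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0
    !grown
  } else !mask
  if (!any(dilute))
    stop("no dilute-phase pixels left after rim exclusion")
  diluteMean <- mean(image[dilute])
  if (diluteMean <= 0)
    stop("dilute-phase mean must be positive for a partition ratio")
  ids <- sort(unique(labels[labels > 0]))
  ratio <- vapply(ids, function(i) mean(image[labels == i]) / diluteMean,
                  numeric(1))
  list(objects = data.frame(label = ids, ratio = ratio),
       diluteMean = diluteMean,
       summary = list(mean_ratio = if (length(ratio)) mean(ratio)
                      else NA_real_))
}

#' Persistence curve from an integrated-density time series
#'
#' Normalizes a per-centrosome (or per-field) integrated-density series
#' to its pre-event value (extrusion into buffer, or dilution), and
#' summarizes the fraction remaining at fixed horizons plus the time of
#' first crossing below one half (linear interpolation), if crossed.
#'
#' @param t Time, s.
#' @param values Integrated density, a.u.
#' @param preEventIndex Index of the pre-event measurement the series is
#'   normalized to.
#' @param horizons Times (s) at which the remaining fraction is reported;
#'   defaults 10 min and 60 min.
#' @return A \linkS4class{PersistenceCurve}.
#' @export
persistenceCurve <- function(t, values, preEventIndex = 1,
                             horizons = c(600, 3600)) {
  if (length(t) != length(values)) stop("t and values must match")
  if (preEventIndex < 1 || preEventIndex > length(values))
    stop("preEventIndex out of range")
  pre <- values[preEventIndex]
  if (!is.finite(pre) || pre <= 0) stop("pre-event value must be positive")
  norm <- values / pre
  fr <- vapply(horizons, function(h) {
    if (h < min(t) || h > max(t)) return(NA_real_)
    stats::approx(t, norm, xout = h)$y
  }, numeric(1))
  names(fr) <- as.character(horizons)
  below <- which(norm < 0.5)
  halfTime <- NA_real_
  if (length(below)) {
    i <- below[1]
    if (i == 1) {
      halfTime <- t[1]
    } else {
      f <- (norm[i - 1] - 0.5) / (norm[i - 1] - norm[i])
      halfTime <- t[i - 1] + f * (t[i] - t[i - 1])
    }
  }
  methods::new("PersistenceCurve", t = as.numeric(t),
               raw = as.numeric(values), normalized = norm,
               fractionRemaining = fr, halfTime = halfTime)
}

setMethod("show", "PersistenceCurve", function(object) {
  cat(sprintf("PersistenceCurve: %d points, t = %g..%g s\n",
              length(object@t), min(object@t), max(object@t)))
  fr <- object@fractionRemaining
  if (length(fr))
    cat("  fraction remaining:",
        paste(sprintf("%s s: %.3g", names(fr), fr), collapse = ", "), "\n")
  if (is.finite(object@halfTime))
    cat(sprintf("  first crossing of 0.5 at t = %.4g s\n", object@halfTime))
})
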