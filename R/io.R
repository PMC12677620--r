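#' Read and write trajectory tables
#'
#' Trajectories travel as CSV with columns \code{trajectory_id},
#' \code{frame}, \code{t_s}, \code{x_um}, \code{y_um}, plus a JSON
#' sidecar (same path with extension \code{.json}) holding the
#' acquisition metadata: \code{dt}, \code{pixel_size},
#' \code{bead_radius_m}, \code{temperature_K}, \code{seed}.
#'
#' @param traj A \linkS4class{TrajectorySet}.
#' @param path CSV file path.
#' @return \code{writeTrajectories} returns \code{path} invisibly;
#'   \code{readTrajectories} returns a \linkS4class{TrajectorySet}.
#' @export
writeTrajectories <- function(traj, path) {
  stopifnot(is(traj, "TrajectorySet"))
  utils::write.csv(traj@data, path, row.names = FALSE)
  meta <- list(dt = traj@dt, pixel_size = traj@pixelSize,
               bead_radius_m = traj@beadRadius,
               temperature_K = traj@temperature, seed = traj@seed)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

.sidecarPath <- function(path) sub("\\.[A-Za-z0-9]+$", ".json", path)

#' @rdname writeTrajectories
#' @export
readTrajectories <- function(path) {
  d <- utils::read.csv(path)
  need <- c("trajectory_id", "frame", "t_s", "x_um", "y_um")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("trajectory CSV lacks column(s): ", paste(missing, collapse = ", "))
  side <- .sidecarPath(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  num <- function(x, default) {
    if (is.null(x) || is.null(x[[1]])) default else as.numeric(x)
  }
  dtGuess <- if (nrow(d) > 1) {
    dd <- diff(d$t_s) / diff(d$frame)
    stats::median(dd[is.finite(dd) & dd > 0])
  } else NA_real_
  methods::new("TrajectorySet", data = d,
               dt = num(meta$dt, dtGuess),
               pixelSize = num(meta$pixel_size, NA_real_),
               beadRadius = num(meta$bead_radius_m, NA_real_),
               temperature = num(meta$temperature_K, NA_real_),
               seed = num(meta$seed, NA_real_))
}

#' Read and write intensity traces
#'
#' CSV with columns \code{t_s} and \code{value}.
#'
#' @param trace An \linkS4class{IntensityTrace}.
#' @param path CSV file path.
#' @param role Role given to a trace read from disk.
#' @return The path (write, invisibly) or an
#'   \linkS4class{IntensityTrace} (read).
#' @export
writeIntensityTrace <- function(trace, path) {
  stopifnot(is(trace, "IntensityTrace"))
  utils::write.csv(data.frame(t_s = trace@t, value = trace@value), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeIntensityTrace
#' @export
readIntensityTrace <- function(path, role = "bleached") {
  d <- utils::read.csv(path)
  if (!all(c("t_s", "value") %in% names(d)))
    stop("trace CSV needs columns t_s and value")
  intensityTrace(d$t_s, d$value, role = role)
}

#' Read and write image stacks as multi-page TIFF
#'
#' 16-bit multi-page TIFF plus the usual JSON sidecar (\code{dt},
#' \code{pixel_size}).  Pixel values are stored as
#' \code{round(value)/65535} and restored on read, so integer photon
#' counts up to 65535 round-trip exactly.
#'
#' @param stack An \linkS4class{ImageStack}.
#' @param path TIFF file path.
#' @return The path (write, invisibly) or an \linkS4class{ImageStack}
#'   (read).
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  nf <- dim(stack@pixels)[3]
  pages <- lapply(seq_len(nf), function(f) {
    pmin(pmax(round(stack@pixels[, , f]), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(dt = stack@dt, pixel_size = stack@pixelSize),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  px <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) px[, , f] <- pages[[f]] * 65535
  side <- .sidecarPath(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  dt <- if (is.null(meta$dt)) 1 else as.numeric(meta$dt)
  ps <- if (is.null(meta$pixel_size)) NA_real_ else
    as.numeric(meta$pixel_size)
  methods::new("ImageStack", pixels = px, dt = dt, pixelSize = ps)
}
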