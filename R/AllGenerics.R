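#' @name vptRheo-accessors
#' @title Accessors for vptRheo data classes
#'
#' @description Slot access for the S4 containers.  \code{trajectories}
#' returns the long-format position table of a \linkS4class{TrajectorySet};
#' \code{frameInterval}, \code{pixelSize}, \code{beadRadius} and
#' \code{temperature} return acquisition metadata; \code{msdLags},
#' \code{msdValues} and \code{msdCounts} read an \linkS4class{MSDCurve};
#' \code{omegas}, \code{elasticModulus}, \code{viscousModulus} and
#' \code{localSlope} read a \linkS4class{ModuliCurves}; \code{etaZero}
#' returns the zero-shear viscosity of a \linkS4class{ViscositySpectrum}
#' or \linkS4class{MaxwellFit}.
#'
#' @param x An object of the documented class.
#' @return The slot value.
NULL

#' @rdname vptRheo-accessors
#' @export
setGeneric("trajectories", function(x) standardGeneric("trajectories"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("nTrajectories", function(x) standardGeneric("nTrajectories"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("beadRadius", function(x) standardGeneric("beadRadius"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("modelKind", function(x) standardGeneric("modelKind"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("plateauModulus", function(x) standardGeneric("plateauModulus"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("relaxationTime", function(x) standardGeneric("relaxationTime"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("diffusionCoefficient",
           function(x) standardGeneric("diffusionCoefficient"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("msdLags", function(x) standardGeneric("msdLags"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("msdValues", function(x) standardGeneric("msdValues"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("msdCounts", function(x) standardGeneric("msdCounts"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("omegas", function(x) standardGeneric("omegas"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("elasticModulus", function(x) standardGeneric("elasticModulus"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("viscousModulus", function(x) standardGeneric("viscousModulus"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("localSlope", function(x) standardGeneric("localSlope"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("isMeasured", function(x) standardGeneric("isMeasured"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("etaZero", function(x) standardGeneric("etaZero"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("plateauRange", function(x) standardGeneric("plateauRange"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname vptRheo-accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' Fit a Maxwell fluid
#'
#' Generic with methods for \linkS4class{ModuliCurves} (default entry
#' point: joint least squares of log G' and log G'' against the Maxwell
#' closed forms) and \linkS4class{MSDCurve} (equivalent time-domain entry
#' point: weighted linear fit of the offset-plus-linear Maxwell MSD).
#'
#' @param object Moduli or MSD data to fit.
#' @param ... Method-specific arguments.
#' @return A \linkS4class{MaxwellFit}.
#' @export
setGeneric("fitMaxwell", function(object, ...) standardGeneric("fitMaxwell"))

#' Detect sub-pixel features
#'
#' Generic with methods for a single frame (matrix) and an
#' \linkS4class{ImageStack}.
#'
#' @param image Matrix or \linkS4class{ImageStack}.
#' @param ... Arguments passed to the matrix method.
#' @return A feature \code{data.frame}; see \code{\link{locateFeatures}}.
#' @export
setGeneric("locateFeatures", function(image, ...)
  standardGeneric("locateFeatures"))
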