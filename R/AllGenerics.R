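#' @name lymphoscope-accessors
#' @title Accessor generics
#' @description Slot accessors for the package's S4 containers.
#' @param object an S4 object from this package.
#' @param ... unused.
#' @return The slot value (see the individual methods).
NULL

#' @rdname lymphoscope-accessors
#' @export
setGeneric("stackData", function(object, ...) standardGeneric("stackData"))

#' @rdname lymphoscope-accessors
#' @export
setGeneric("pixelPitch", function(object, ...) standardGeneric("pixelPitch"))

#' @rdname lymphoscope-accessors
#' @export
setGeneric("frameInterval",
           function(object, ...) standardGeneric("frameInterval"))

#' @rdname lymphoscope-accessors
#' @export
setGeneric("band", function(object, ...) standardGeneric("band"))

#' @rdname lymphoscope-accessors
#' @export
setGeneric("nFrames", function(object, ...) standardGeneric("nFrames"))

#' @rdname lymphoscope-accessors
#' @export
setGeneric("tsValues", function(object, ...) standardGeneric("tsValues"))

#' @rdname lymphoscope-accessors
#' @export
setGeneric("provenance", function(object, ...) standardGeneric("provenance"))

#' @rdname lymphoscope-accessors
#' @export
setGeneric("maskMatrix", function(object, ...) standardGeneric("maskMatrix"))

#' @rdname lymphoscope-accessors
#' @export
setGeneric("maskIndices", function(object, ...) standardGeneric("maskIndices"))

#' @rdname lymphoscope-accessors
#' @export
setGeneric("peakTable", function(object, ...) standardGeneric("peakTable"))

#' @rdname lymphoscope-accessors
#' @export
setGeneric("positions", function(object, ...) standardGeneric("positions"))

#' @rdname lymphoscope-accessors
#' @export
setGeneric("intensities", function(object, ...) standardGeneric("intensities"))

#' True bolus arrival times
#'
#' Times at which each simulated bolus centre passes a given arclength on a
#' vessel centerline: entry time plus arclength divided by velocity.
#'
#' @param object a \code{\link{GroundTruth}}.
#' @param vessel vessel index.
#' @param s arclength position(s) on that vessel's centerline, mm.
#' @return Numeric vector (one \code{s}) or matrix (rows = boluses, cols =
#'   \code{s}) of arrival times in seconds, ordered by bolus start time.
#' @export
setGeneric("arrivalTimes",
           function(object, vessel = 1L, s = 0) standardGeneric("arrivalTimes"))
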