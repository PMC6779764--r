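#' @include AllClasses.R
NULL

#' Accessors for fitime classes
#'
#' Small accessor generics: \code{trials()} and \code{spikeUnits()} extract
#' the trial table and unit list from a \linkS4class{FiSession};
#' \code{curvatureValue()} the scalar from a \linkS4class{CurvatureResult};
#' \code{startTime()} the estimate from a \linkS4class{StartTimeResult};
#' \code{truth()} the generative ground truth of a synthetic
#' \linkS4class{SpikeUnit}; \code{sortOrder()} the PC1 row permutation of a
#' \linkS4class{PethMatrix}.
#'
#' @param x the object.
#' @return the extracted component.
#' @name accessors
#' @aliases trials spikeUnits curvatureValue startTime truth sortOrder
NULL

#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @rdname accessors
#' @export
setGeneric("spikeUnits", function(x) standardGeneric("spikeUnits"))

#' @rdname accessors
#' @export
setGeneric("curvatureValue", function(x) standardGeneric("curvatureValue"))

#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))

#' @rdname accessors
#' @export
setGeneric("sortOrder", function(x) standardGeneric("sortOrder"))

#' @rdname accessors
#' @export
setMethod("trials", "FiSession", function(x) x@trials)

#' @rdname accessors
#' @export
setMethod("spikeUnits", "FiSession", function(x) x@units)

#' @rdname accessors
#' @export
setMethod("curvatureValue", "CurvatureResult", function(x) x@value)

#' @rdname accessors
#' @export
setMethod("startTime", "StartTimeResult", function(x) x@start)

#' @rdname accessors
#' @export
setMethod("truth", "SpikeUnit", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("sortOrder", "PethMatrix", function(x) x@sortOrder)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nAnimals, "animals (", object@nOpsin, "opsin ),",
      object@nSessionsPerCondition, "session(s)/drug,",
      object@sessionMinutes, "min, FI", object@interval, "s\n")
  cat("  start_mu (s):\n")
  print(object@startMu)
  cat("  units:", object@nUnits, " fracRamping:", object@fracRamping,
      " fracFsi:", round(object@fracFsi, 3), "\n")
  invisible(NULL)
})

setMethod("show", "SpikeUnit", function(object) {
  cat("SpikeUnit", object@unitId, "(", object@sessionId, "):",
      length(object@spikeTimes), "spikes, mean rate",
      round(object@meanRate, 3), "Hz\n")
  invisible(NULL)
})

setMethod("show", "FiSession", function(object) {
  cat("FiSession:", nrow(object@trials), "trials,",
      length(unique(object@trials$session_id)), "session(s),",
      length(object@units), "units\n")
  invisible(NULL)
})

setMethod("show", "CurvatureResult", function(object) {
  cat("CurvatureResult [", object@method, "]: ",
      if (object@defined) signif(object@value, 4) else "undefined (0 responses)",
      " (n = ", object@totalResponses, " responses, ",
      object@nSegments, " segments)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "StartTimeResult", function(object) {
  if (object@valid)
    cat("StartTimeResult: start =", round(object@start, 3), "s, objective =",
        signif(object@objective, 4), ",", object@nResponses, "responses\n")
  else
    cat("StartTimeResult: invalid (", object@nResponses, "responses )\n")
  invisible(NULL)
})

setMethod("show", "PethMatrix", function(object) {
  cat("PethMatrix:", nrow(object), "units x", ncol(object), "bins (",
      object@bin * 1000, "ms bins, bandwidth", object@bandwidth, "s )\n")
  callNextMethod()
  invisible(NULL)
})
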