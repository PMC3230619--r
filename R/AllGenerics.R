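#' Accessors for bioturbation objects
#'
#' Small generic accessors used instead of direct slot access:
#' `tracerCounts()` / `nonmarkedCounts()` return the per-layer particle counts
#' of a [latticeState()], `layerCapacity()` its capacity `w`;
#' `profileCounts()` returns the depth-by-time matrix of a [profileSeries()],
#' `nLayers()` / `nTimes()` its dimensions, `timesMin()` the column times in
#' minutes and `depthsMm()` the depth of each layer midpoint in mm;
#' `paramValues()` returns the named parameter vector of a [modelParams()] or
#' of a fit result; `fitReplicates()` the per-replicate table of a fit.
#'
#' @param object a bioturb S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tracerCounts", function(object) standardGeneric("tracerCounts"))
#' @rdname accessors
#' @export
setGeneric("nonmarkedCounts", function(object) standardGeneric("nonmarkedCounts"))
#' @rdname accessors
#' @export
setGeneric("layerCapacity", function(object) standardGeneric("layerCapacity"))
#' @rdname accessors
#' @export
setGeneric("profileCounts", function(object) standardGeneric("profileCounts"))
#' @rdname accessors
#' @export
setGeneric("nLayers", function(object) standardGeneric("nLayers"))
#' @rdname accessors
#' @export
setGeneric("nTimes", function(object) standardGeneric("nTimes"))
#' @rdname accessors
#' @export
setGeneric("timesMin", function(object) standardGeneric("timesMin"))
#' @rdname accessors
#' @export
setGeneric("depthsMm", function(object) standardGeneric("depthsMm"))
#' @rdname accessors
#' @export
setGeneric("paramValues", function(object) standardGeneric("paramValues"))
#' @rdname accessors
#' @export
setGeneric("fitReplicates", function(object) standardGeneric("fitReplicates"))
#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname accessors
setMethod("tracerCounts", "LatticeState", function(object) object@tracer)
#' @rdname accessors
setMethod("nonmarkedCounts", "LatticeState", function(object) object@nonmarked)
#' @rdname accessors
setMethod("layerCapacity", "LatticeState", function(object) object@capacity)

#' @rdname accessors
setMethod("profileCounts", "ProfileSeries", function(object) object@counts)
#' @rdname accessors
setMethod("nLayers", "ProfileSeries", function(object) nrow(object@counts))
#' @rdname accessors
setMethod("nTimes", "ProfileSeries", function(object) ncol(object@counts))
#' @rdname accessors
setMethod("timesMin", "ProfileSeries", function(object)
  (seq_len(ncol(object@counts)) - 1) * object@dtMin)
#' @rdname accessors
setMethod("depthsMm", "ProfileSeries", function(object)
  (seq_len(nrow(object@counts)) - 0.5) * object@layerHeightMm)

#' @rdname accessors
setMethod("paramValues", "ModelParams", function(object)
  c(activity = object@activity, distance = object@distance,
    downwards = object@downwards, range = object@range,
    tracerdif = object@tracerdif))
#' @rdname accessors
setMethod("paramValues", "FitResult", function(object) paramValues(object@params))
#' @rdname accessors
setMethod("fitReplicates", "FitResult", function(object) object@replicates)
#' @rdname accessors
setMethod("objectiveValue", "FitResult", function(object) object@objective)
#' @rdname accessors
setMethod("objectiveValue", "DiffusionFit", function(object) object@objective)

#' Maximum tracer penetration depth
#'
#' Depth (mm below the sediment-water interface) of the deepest layer with a
#' non-zero tracer count in the final time column of a profile. Returns 0 for
#' an all-zero final column.
#'
#' @param object a [profileSeries()].
#' @return penetration depth in mm.
#' @export
setGeneric("penetrationDepthMm", function(object) standardGeneric("penetrationDepthMm"))

#' @rdname penetrationDepthMm
setMethod("penetrationDepthMm", "ProfileSeries", function(object) {
  lastCol <- object@counts[, ncol(object@counts)]
  nz <- which(lastCol > 0)
  if (!length(nz)) return(0)
  max(nz) * object@layerHeightMm
})
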