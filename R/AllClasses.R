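#' @import methods
#' @importFrom stats optim optimize rbinom rpois rgeom rexp runif setNames var
NULL

## ---------------------------------------------------------------------------
## ModelParams
## ---------------------------------------------------------------------------

#' Behavioural parameters of the bioturbation lattice model
#'
#' Holds the five parameters that govern particle reworking:
#' \describe{
#'   \item{activity}{probability per tracer particle per time step of being
#'     actively displaced (dimensionless, in \[0, 1\]). Its complement scales
#'     the expected rest period of a particle.}
#'   \item{distance}{mean displacement magnitude, in sediment layers
#'     (positive real; the magnitude distribution is configured in
#'     [simConfig()]).}
#'   \item{downwards}{probability that a displaced particle moves down rather
#'     than up (Bernoulli direction trial; in \[0, 1\]).}
#'   \item{range}{fraction of the total depth open to active reworking, in
#'     (0, 1\]; layers below `round(range * d)` are never displacement
#'     sources.}
#'   \item{tracerdif}{relative selection weight of a tracer particle versus a
#'     non-marked particle during passive rebalancing, in (0, 1\]. Values
#'     below 1 make tracers lag behind the compensatory particle flow, which
#'     is what produces subsurface tracer peaks.}
#' }
#'
#' @param activity,distance,downwards,range,tracerdif numeric scalars, see
#'   Details above.
#' @return A `ModelParams` object.
#' @examples
#' modelParams(activity = 0.674, distance = 4.242, tracerdif = 0.929)
#' @export
modelParams <- function(activity = 0.5, distance = 1, downwards = 0.5,
                        range = 1, tracerdif = 1) {
  obj <- new("ModelParams",
             activity = as.numeric(activity), distance = as.numeric(distance),
             downwards = as.numeric(downwards), range = as.numeric(range),
             tracerdif = as.numeric(tracerdif))
  obj
}

#' @rdname modelParams
#' @export
setClass("ModelParams",
         representation(activity = "numeric", distance = "numeric",
                        downwards = "numeric", range = "numeric",
                        tracerdif = "numeric"))

setValidity("ModelParams", function(object) {
  probs <- c(activity = object@activity, downwards = object@downwards)
  msgs <- character()
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
      msgs <- c(msgs, sprintf("'%s' must be a single value in [0, 1]", nm))
  }
  if (length(object@distance) != 1L || !is.finite(object@distance) ||
      object@distance <= 0)
    msgs <- c(msgs, "'distance' must be a single positive value")
  if (length(object@range) != 1L || !is.finite(object@range) ||
      object@range <= 0 || object@range > 1)
    msgs <- c(msgs, "'range' must be a single value in (0, 1]")
  if (length(object@tracerdif) != 1L || !is.finite(object@tracerdif) ||
      object@tracerdif <= 0 || object@tracerdif > 1)
    msgs <- c(msgs, "'tracerdif' must be a single value in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

paramNames <- function() c("activity", "distance", "downwards", "range", "tracerdif")

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Lattice geometry, physical scales and time stepping
#'
#' @param d number of sediment layers (rows); layer 0 sits at the
#'   sediment-water interface and indices increase downward.
#' @param w layer capacity in particles (lattice width in cells).
#' @param dLum number of uppermost layers initially filled with tracer.
#' @param layerHeightMm physical height of one layer in mm (default 0.073,
#'   one camera pixel in the worked example).
#' @param dtMin duration of one time step in minutes.
#' @param nSteps number of simulated time steps.
#' @param seed RNG seed for [simulateProfile()]; `NA` leaves the global RNG
#'   stream untouched.
#' @param magnitudeDist displacement-magnitude distribution: `"poisson"`
#'   (default; mean = `distance`, draws of 0 leave the particle in place),
#'   `"fixed"` (integer part of `distance` plus a Bernoulli fractional step),
#'   or `"geometric"` (mean = `distance`).
#' @return A `SimConfig` object.
#' @examples
#' simConfig(d = 149, w = 298, dLum = 20, nSteps = 24, seed = 1)
#' @export
simConfig <- function(d, w, dLum, layerHeightMm = 0.073, dtMin = 5,
                      nSteps = 24, seed = NA_integer_,
                      magnitudeDist = c("poisson", "fixed", "geometric")) {
  magnitudeDist <- match.arg(magnitudeDist)
  new("SimConfig",
      d = as.integer(d), w = as.integer(w), dLum = as.integer(dLum),
      layerHeightMm = as.numeric(layerHeightMm), dtMin = as.numeric(dtMin),
      nSteps = as.integer(nSteps), seed = as.integer(seed),
      magnitudeDist = magnitudeDist)
}

#' @rdname simConfig
#' @export
setClass("SimConfig",
         representation(d = "integer", w = "integer", dLum = "integer",
                        layerHeightMm = "numeric", dtMin = "numeric",
                        nSteps = "integer", seed = "integer",
                        magnitudeDist = "character"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (length(object@d) != 1L || is.na(object@d) || object@d < 1L)
    msgs <- c(msgs, "'d' must be a single integer >= 1")
  if (length(object@w) != 1L || is.na(object@w) || object@w < 1L)
    msgs <- c(msgs, "'w' must be a single integer >= 1")
  if (length(object@dLum) != 1L || is.na(object@dLum) || object@dLum < 0L ||
      (!is.na(object@d) && length(object@d) == 1L && object@dLum > object@d))
    msgs <- c(msgs, "'dLum' must be a single integer in [0, d]")
  if (length(object@nSteps) != 1L || is.na(object@nSteps) || object@nSteps < 0L)
    msgs <- c(msgs, "'nSteps' must be a single integer >= 0")
  if (length(object@layerHeightMm) != 1L || !is.finite(object@layerHeightMm) ||
      object@layerHeightMm <= 0)
    msgs <- c(msgs, "'layerHeightMm' must be a single positive value")
  if (length(object@dtMin) != 1L || !is.finite(object@dtMin) || object@dtMin <= 0)
    msgs <- c(msgs, "'dtMin' must be a single positive value")
  if (!object@magnitudeDist %in% c("poisson", "fixed", "geometric"))
    msgs <- c(msgs, "'magnitudeDist' must be one of poisson, fixed, geometric")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## LatticeState and DisplacementLedger
## ---------------------------------------------------------------------------

#' Per-layer particle counts of the sediment column
#'
#' A `LatticeState` records, for every sediment layer, how many tracer
#' (luminophore) and how many non-marked particles it contains. Layer 1 of the
#' vectors is the sediment-water interface; indices increase downward. After a
#' complete model step every layer holds exactly `capacity` particles.
#'
#' @param tracer integer vector of per-layer tracer counts.
#' @param nonmarked integer vector of per-layer non-marked counts.
#' @param capacity layer capacity `w`.
#' @return A `LatticeState` object.
#' @seealso [initLattice()], [stepLattice()]
#' @export
latticeState <- function(tracer, nonmarked, capacity) {
  new("LatticeState", tracer = as.integer(round(tracer)),
      nonmarked = as.integer(round(nonmarked)), capacity = as.integer(capacity))
}

#' @rdname latticeState
#' @export
setClass("LatticeState",
         representation(tracer = "integer", nonmarked = "integer",
                        capacity = "integer"))

setValidity("LatticeState", function(object) {
  msgs <- character()
  if (length(object@tracer) != length(object@nonmarked))
    msgs <- c(msgs, "'tracer' and 'nonmarked' must have equal length")
  if (anyNA(object@tracer) || any(object@tracer < 0L))
    msgs <- c(msgs, "tracer counts must be non-negative integers")
  if (anyNA(object@nonmarked) || any(object@nonmarked < 0L))
    msgs <- c(msgs, "non-marked counts must be non-negative integers")
  if (length(object@capacity) != 1L || is.na(object@capacity) ||
      object@capacity < 1L)
    msgs <- c(msgs, "'capacity' must be a single integer >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Record of one round of active tracer displacement
#'
#' Per-layer removals and additions of tracer particles produced by
#' [drawActiveDisplacements()]. Active displacement conserves tracer count, so
#' total removals always equal total additions, and no entry refers to a layer
#' outside the column.
#'
#' @param removals,additions integer vectors of equal length `d`.
#' @return A `DisplacementLedger` object.
#' @export
displacementLedger <- function(removals, additions) {
  new("DisplacementLedger", removals = as.integer(removals),
      additions = as.integer(additions))
}

#' @rdname displacementLedger
#' @export
setClass("DisplacementLedger",
         representation(removals = "integer", additions = "integer"))

setValidity("DisplacementLedger", function(object) {
  msgs <- character()
  if (length(object@removals) != length(object@additions))
    msgs <- c(msgs, "'removals' and 'additions' must have equal length")
  if (anyNA(object@removals) || any(object@removals < 0L) ||
      anyNA(object@additions) || any(object@additions < 0L))
    msgs <- c(msgs, "ledger entries must be non-negative integers")
  if (sum(object@removals) != sum(object@additions))
    msgs <- c(msgs, "total removals must equal total additions")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## ProfileSeries
## ---------------------------------------------------------------------------

#' Depth-by-time matrix of tracer counts
#'
#' The central data container: rows are sediment layers (row 1 at the
#' sediment-water interface), columns are time points at `dtMin`-minute
#' spacing, and cells hold tracer (luminophore pixel) counts. Both observed
#' profiles read with [readProfile()] and simulated profiles from
#' [simulateProfile()] or [diffuseTracer()] use this class.
#'
#' @param counts non-negative numeric matrix, layers in rows.
#' @param dtMin spacing between columns in minutes.
#' @param layerHeightMm physical layer height in mm.
#' @return A `ProfileSeries` object.
#' @export
profileSeries <- function(counts, dtMin = 5, layerHeightMm = 0.073) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  dimnames(counts) <- NULL
  new("ProfileSeries", counts = counts, dtMin = as.numeric(dtMin),
      layerHeightMm = as.numeric(layerHeightMm))
}

#' @rdname profileSeries
#' @export
setClass("ProfileSeries",
         representation(counts = "matrix", dtMin = "numeric",
                        layerHeightMm = "numeric"))

setValidity("ProfileSeries", function(object) {
  msgs <- character()
  if (!is.numeric(object@counts))
    msgs <- c(msgs, "'counts' must be numeric")
  else if (anyNA(object@counts) || any(object@counts < 0))
    msgs <- c(msgs, "'counts' must be non-negative and free of NA")
  if (length(object@dtMin) != 1L || !is.finite(object@dtMin) || object@dtMin <= 0)
    msgs <- c(msgs, "'dtMin' must be a single positive value")
  if (length(object@layerHeightMm) != 1L || !is.finite(object@layerHeightMm) ||
      object@layerHeightMm <= 0)
    msgs <- c(msgs, "'layerHeightMm' must be a single positive value")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## FitResult, SensitivityGrid, DiffusionFit
## ---------------------------------------------------------------------------

#' Result of a calibration run
#'
#' Returned by [fitSANN()] and [fitBFGS()]. `params` is the headline point
#' estimate (best parameters for simulated annealing; per-replicate means for
#' the quasi-Newton refinement), `objective` the sum of squares at that
#' estimate, `trace` the sequence of evaluated parameter sets, and
#' `replicates` one row per independent refinement run. `paramSD` holds the
#' across-replicate standard deviation of each free parameter.
#'
#' @export
setClass("FitResult",
         representation(params = "ModelParams", objective = "numeric",
                        trace = "data.frame", replicates = "data.frame",
                        paramSD = "numeric", fixed = "character",
                        widthFactor = "numeric", method = "character"))

setValidity("FitResult", function(object) {
  msgs <- character()
  if (length(object@objective) != 1L || !is.finite(object@objective) ||
      object@objective < 0)
    msgs <- c(msgs, "'objective' must be a single non-negative value")
  if (length(object@paramSD) && any(object@paramSD < 0, na.rm = TRUE))
    msgs <- c(msgs, "'paramSD' must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Objective surface on a local sensitivity grid
#'
#' A grid of sum-of-squares objective values over `distance` (rows) and
#' `tracerdif` (columns) around a fitted optimum, plus the location of the
#' grid minimum (row-major first-encountered tie-break).
#'
#' @export
setClass("SensitivityGrid",
         representation(distanceValues = "numeric", tracerdifValues = "numeric",
                        objective = "matrix", minIndex = "integer",
                        minDistance = "numeric", minTracerdif = "numeric"))

setValidity("SensitivityGrid", function(object) {
  msgs <- character()
  if (!all(dim(object@objective) ==
           c(length(object@distanceValues), length(object@tracerdifValues))))
    msgs <- c(msgs, "objective matrix shape must match the axis lengths")
  if (length(object@minIndex) != 2L)
    msgs <- c(msgs, "'minIndex' must be (row, column)")
  else if (!isTRUE(all.equal(object@objective[object@minIndex[1], object@minIndex[2]],
                             min(object@objective))))
    msgs <- c(msgs, "'minIndex' must point at the matrix minimum")
  if (length(msgs)) msgs else TRUE
})

#' Fitted biodiffusion reference model
#'
#' Result of [fitDb()]: the biodiffusion coefficient `db` in layers^2 per
#' minute (and `dbMm2PerMin` in mm^2 per minute), the total sum-of-squares
#' objective, and its decomposition into per-time-point sums of squares.
#'
#' @export
setClass("DiffusionFit",
         representation(db = "numeric", dbMm2PerMin = "numeric",
                        objective = "numeric", perTimeSos = "numeric"))

setValidity("DiffusionFit", function(object) {
  msgs <- character()
  if (length(object@db) != 1L || !is.finite(object@db) || object@db < 0)
    msgs <- c(msgs, "'db' must be a single non-negative value")
  if (!isTRUE(all.equal(object@objective, sum(object@perTimeSos))))
    msgs <- c(msgs, "'objective' must equal the sum of 'perTimeSos'")
  if (length(msgs)) msgs else TRUE
})
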