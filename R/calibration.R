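## Calibration of the lattice model against an observed tracer profile:
## sum-of-squares objective, coarse parameter scan, simulated annealing,
## quasi-Newton refinement with replicates, and the local sensitivity grid.

#' Box bounds used by the fitting routines
#'
#' Named lower/upper vectors for the five model parameters. `distance` is
#' bounded below by a small positive epsilon; the probability-type parameters
#' live in \[0, 1\] boxes and `tracerdif`/`range` are kept strictly positive.
#'
#' @return list with `lower` and `upper` named numeric vectors.
#' @export
defaultParamBounds <- function() {
  list(lower = c(activity = 0, distance = 0.05, downwards = 0,
                 range = 1e-6, tracerdif = 1e-6),
       upper = c(activity = 1, distance = 20, downwards = 1,
                 range = 1, tracerdif = 1))
}

## Fold a proposal back into [lo, hi] by reflection at the box walls.
reflectIntoBounds <- function(x, lo, hi) {
  r <- hi - lo
  y <- (x - lo) %% (2 * r)
  out <- ifelse(y > r, 2 * r - y, y) + lo
  ifelse(r > 0, out, lo)
}

## Replace the named free parameters of a ModelParams with new values.
replaceParams <- function(params, values) {
  for (nm in names(values)) slot(params, nm) <- unname(values[[nm]])
  validObject(params)
  params
}

#' Sum-of-squares objective between observed and simulated profiles
#'
#' Simulates the lattice model under `params`/`config`, rescales the
#' simulated counts by `widthFactor` (the model typically runs on a column
#' `widthFactor` times narrower than the imaged sediment, and mixing events
#' are assumed homogeneous across the width), and returns the sum over all
#' layers and compared time points of the squared count differences.
#'
#' Simulated column \eqn{k} is compared with the observed column at the same
#' elapsed time; if the observed series has more columns than
#' `config@nSteps + 1`, only every `stride`-th observed column is used,
#' starting at time 0.
#'
#' @param params a [modelParams()].
#' @param observed a [profileSeries()] of observed counts.
#' @param config a [simConfig()]; `config@d` must equal the observed layer
#'   count.
#' @param widthFactor multiplier applied to simulated counts before
#'   comparison (default 10).
#' @param seed seed for the embedded simulation; defaults to `config@seed`.
#'   Fixing it gives a deterministic (common-random-numbers) objective.
#' @param stride subsampling stride through the observed columns.
#' @param nSim number of simulation replicates averaged per evaluation
#'   (seeds `seed .. seed + nSim - 1`); values above 1 reduce the Monte
#'   Carlo noise of the objective.
#' @return a single non-negative number.
#' @export
ssqObjective <- function(params, observed, config, widthFactor = 10,
                         seed = config@seed, stride = 1L, nSim = 1L) {
  obs <- profileCounts(observed)
  if (nrow(obs) != config@d)
    stopUsage("shape mismatch: observed has %d layers, config expects %d",
              nrow(obs), config@d)
  idx <- seq.int(1L, by = as.integer(stride), length.out = config@nSteps + 1L)
  if (max(idx) > ncol(obs))
    stopUsage(paste0("shape mismatch: observed has %d time columns but ",
                     "nSteps = %d with stride %d needs %d"),
              ncol(obs), config@nSteps, stride, max(idx))
  obs <- obs[, idx, drop = FALSE]
  cfg <- config
  vals <- vapply(seq_len(nSim), function(r) {
    cfg@seed <- as.integer(seed) + r - 1L
    sim <- simulateProfile(params, cfg)
    sum((obs - widthFactor * profileCounts(sim))^2)
  }, numeric(1))
  mean(vals)
}

#' Default coarse scan grid
#'
#' An 8 x 8 x 8 grid (512 combinations) over `activity` in \[0.1, 0.9\],
#' `distance` in \[1, 8\] and `tracerdif` in \[0.6, 1.0\], used by
#' [scanParameters()] for a first rough picture of the objective surface.
#'
#' @return a data frame with one row per parameter combination.
#' @export
defaultScanGrid <- function() {
  expand.grid(activity = seq(0.1, 0.9, length.out = 8),
              distance = seq(1, 8, length.out = 8),
              tracerdif = seq(0.6, 1.0, length.out = 8),
              KEEP.OUT.ATTRS = FALSE)
}

#' Evaluate the objective over a grid of parameter combinations
#'
#' One objective evaluation per grid row, all under the same fixed seed
#' (common random numbers) so combinations are compared on identical
#' realisations of the stochastic model. The best combination is the first
#' minimum in grid-row order.
#'
#' @param observed,config,widthFactor,stride see [ssqObjective()].
#' @param grid data frame whose columns are a subset of the parameter names;
#'   parameters absent from the grid are taken from `base`.
#' @param base a [modelParams()] supplying the non-scanned parameters.
#' @param seed fixed seed shared by all evaluations.
#' @return list with `table` (grid plus an `objective` column), `best`
#'   (a [modelParams()]) and `bestIndex` (row number of the minimum).
#' @export
scanParameters <- function(observed, config, grid = defaultScanGrid(),
                           base = modelParams(), widthFactor = 10,
                           seed = 1L, stride = 1L) {
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    stopUsage("scan grid must be a non-empty data frame")
  bad <- setdiff(names(grid), paramNames())
  if (length(bad))
    stopUsage("unknown parameter(s) in scan grid: %s", paste(bad, collapse = ", "))
  objective <- vapply(seq_len(nrow(grid)), function(i) {
    p <- replaceParams(base, as.list(grid[i, , drop = FALSE]))
    ssqObjective(p, observed, config, widthFactor, seed = seed, stride = stride)
  }, numeric(1))
  bestIndex <- which.min(objective)        # first minimum in grid order
  best <- replaceParams(base, as.list(grid[bestIndex, , drop = FALSE]))
  list(table = cbind(grid, objective = objective),
       best = best, bestIndex = bestIndex)
}

## Build the traced, reflected objective closure over the free parameters.
## `objectiveFn`, when supplied, replaces the simulation-based objective
## (used for deterministic test stubs); it receives the named free-parameter
## vector after reflection into bounds.
makeClosure <- function(start, free, observed, config, widthFactor, seed,
                        stride, bounds, objectiveFn, traceEnv, nSim = 1L) {
  lo <- bounds$lower[free]; hi <- bounds$upper[free]
  function(par) {
    par <- reflectIntoBounds(par, lo, hi)
    names(par) <- free
    val <- if (is.null(objectiveFn)) {
      ssqObjective(replaceParams(start, par), observed, config,
                   widthFactor, seed = seed, stride = stride, nSim = nSim)
    } else {
      objectiveFn(par)
    }
    traceEnv$rows[[length(traceEnv$rows) + 1L]] <- c(par, objective = val)
    val
  }
}

traceToFrame <- function(traceEnv, free) {
  if (!length(traceEnv$rows)) {
    return(data.frame(eval = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, traceEnv$rows))
  cbind(eval = seq_len(nrow(df)), df)
}

checkStart <- function(par0, free, bounds) {
  lo <- bounds$lower[free]; hi <- bounds$upper[free]
  if (any(par0 < lo | par0 > hi))
    stopUsage("start value out of bounds for: %s",
              paste(free[par0 < lo | par0 > hi], collapse = ", "))
}

#' Simulated-annealing calibration
#'
#' Broadly locates the global minimum of the sum-of-squares objective over
#' the free parameters using simulated annealing ([stats::optim()] method
#' `"SANN"`), with proposals reflected back into the parameter box. The
#' objective is evaluated under common random numbers (one fixed seed per
#' run), and the best evaluated parameter set is returned.
#'
#' @param start a [modelParams()] giving start values; parameters named in
#'   `fixed` are held at their `start` values.
#' @param observed,config,widthFactor,stride see [ssqObjective()].
#' @param fixed character vector of parameter names to hold constant
#'   (default: everything except `distance` and `tracerdif`).
#' @param seed seed for the common-random-numbers objective.
#' @param control list merged over the defaults
#'   `list(maxit = 300, temp = NA, tmax = 5)` and passed to
#'   [stats::optim()]; `temp = NA` scales the initial temperature to 5\% of
#'   the objective at the start values, so the acceptance rule works on the
#'   natural scale of the problem.
#' @param bounds parameter box, see [defaultParamBounds()].
#' @param objectiveFn optional replacement objective
#'   `function(namedFreeParams) -> value` (used for deterministic stubs).
#' @param nSim simulation replicates averaged per evaluation, see
#'   [ssqObjective()].
#' @param proposalSd per-parameter standard deviation of the Gaussian
#'   proposal kernel; default 5\% of each parameter's box width.
#' @return a [FitResult-class] object.
#' @export
fitSANN <- function(start, observed, config,
                    fixed = c("activity", "downwards", "range"),
                    widthFactor = 10, stride = 1L, seed = 1L,
                    control = list(), bounds = defaultParamBounds(),
                    objectiveFn = NULL, nSim = 1L, proposalSd = NULL) {
  validObject(start)
  free <- setdiff(paramNames(), fixed)
  if (!length(free)) stopUsage("no free parameters left to fit")
  par0 <- paramValues(start)[free]
  checkStart(par0, free, bounds)
  ctrl <- utils::modifyList(list(maxit = 300, temp = NA, tmax = 5), control)
  traceEnv <- new.env(parent = emptyenv()); traceEnv$rows <- list()
  fn <- makeClosure(start, free, observed, config, widthFactor, seed, stride,
                    bounds, objectiveFn, traceEnv, nSim = nSim)
  f0 <- fn(par0)
  if (!is.finite(f0))
    stopNumeric("objective is not finite at the start values (%g)", f0)
  if (is.na(ctrl$temp)) ctrl$temp <- max(0.05 * f0, 1e-8)
  if (is.null(proposalSd))
    proposalSd <- 0.05 * (bounds$upper[free] - bounds$lower[free])
  propose <- function(par, ...) par + stats::rnorm(length(par), 0, proposalSd)
  optim(par0, fn, gr = propose, method = "SANN", control = ctrl)
  tr <- traceToFrame(traceEnv, free)
  bestRow <- which.min(tr$objective)
  bestPar <- unlist(tr[bestRow, free, drop = FALSE])
  params <- replaceParams(start, bestPar)
  new("FitResult", params = params, objective = tr$objective[bestRow],
      trace = tr,
      replicates = data.frame(replicate = 1L, t(bestPar),
                              objective = tr$objective[bestRow]),
      paramSD = numeric(0), fixed = as.character(fixed),
      widthFactor = widthFactor, method = "SANN")
}

#' Quasi-Newton refinement with replicate runs
#'
#' Refines a calibration (typically the [fitSANN()] result) with the BFGS
#' quasi-Newton algorithm of [stats::optim()]. The stochastic objective is
#' made piecewise-deterministic by common random numbers: within each
#' replicate every evaluation reuses one fixed seed, so finite-difference
#' gradients are meaningful. `nReplicates` independent refinements (each with
#' its own seed) quantify the residual stochastic uncertainty; the headline
#' estimate is the per-parameter replicate mean and `paramSD` the replicate
#' standard deviation.
#'
#' @inheritParams fitSANN
#' @param nReplicates number of independent refinement runs (>= 1).
#' @param seed base seed; replicate `r` uses `seed + r - 1`.
#' @param control list merged over the defaults (`maxit = 40`, per-parameter
#'   finite-difference steps `ndeps` of 0.5\% of the box width).
#' @return a [FitResult-class] object; `fitReplicates()` returns the
#'   per-replicate optima.
#' @export
fitBFGS <- function(start, observed, config,
                    fixed = c("activity", "downwards", "range"),
                    nReplicates = 10L, widthFactor = 10, stride = 1L,
                    seed = 1L, control = list(),
                    bounds = defaultParamBounds(), objectiveFn = NULL,
                    nSim = 1L) {
  validObject(start)
  if (nReplicates < 1L) stopUsage("'nReplicates' must be >= 1")
  free <- setdiff(paramNames(), fixed)
  if (!length(free)) stopUsage("no free parameters left to fit")
  par0 <- paramValues(start)[free]
  checkStart(par0, free, bounds)
  boxWidth <- bounds$upper[free] - bounds$lower[free]
  ## coarse finite-difference steps: the common-random-number surface is
  ## piecewise deterministic but jagged at fine scales, so the gradient is
  ## estimated over steps wide enough to see the underlying trend
  ctrl <- utils::modifyList(
    list(maxit = 30, ndeps = pmax(0.0125 * boxWidth, 1e-4), reltol = 1e-6),
    control)
  ctrl$parscale <- boxWidth / 4

  reps <- vector("list", nReplicates)
  traces <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    traceEnv <- new.env(parent = emptyenv()); traceEnv$rows <- list()
    fn <- makeClosure(start, free, observed, config, widthFactor,
                      seed = as.integer(seed) + r - 1L, stride,
                      bounds, objectiveFn, traceEnv, nSim = nSim)
    f0 <- fn(par0)
    if (!is.finite(f0))
      stopNumeric("objective is not finite at the start values (%g)", f0)
    res <- optim(par0, fn, method = "BFGS", control = ctrl)
    parHat <- reflectIntoBounds(res$par, bounds$lower[free], bounds$upper[free])
    names(parHat) <- free
    ## keep the best evaluated point of the replicate, not the last iterate:
    ## on a jagged surface the final line search can end uphill
    tr <- traceToFrame(traceEnv, free)
    bestRow <- which.min(tr$objective)
    bestPar <- unlist(tr[bestRow, free, drop = FALSE])
    if (tr$objective[bestRow] < res$value) {
      parHat <- bestPar
      res$value <- tr$objective[bestRow]
    }
    reps[[r]] <- data.frame(replicate = r, t(parHat), objective = res$value)
    tr$replicate <- r
    traces[[r]] <- tr
  }
  repDf <- do.call(rbind, reps)
  means <- vapply(free, function(nm) mean(repDf[[nm]]), numeric(1))
  sds <- vapply(free, function(nm) stats::sd(repDf[[nm]]), numeric(1))
  if (nReplicates == 1L) sds[] <- 0
  params <- replaceParams(start, means)
  new("FitResult", params = params, objective = mean(repDf$objective),
      trace = do.call(rbind, traces), replicates = repDf,
      paramSD = sds, fixed = as.character(fixed),
      widthFactor = widthFactor, method = "BFGS")
}

#' Convert a displacement distance from layers to millimetres
#'
#' @param distanceLayers displacement in sediment layers (>= 0).
#' @param layerHeightMm physical height of one layer in mm (>= 0).
#' @return distance in mm.
#' @examples
#' layersToMm(4.30, 0.073) # 0.314 mm
#' @export
layersToMm <- function(distanceLayers, layerHeightMm) {
  if (any(distanceLayers < 0) || any(layerHeightMm < 0))
    stopUsage("'distanceLayers' and 'layerHeightMm' must be non-negative")
  distanceLayers * layerHeightMm
}

#' Local sensitivity grid around a fitted optimum
#'
#' Evaluates the objective on all combinations of `distance` varied from
#' -30\% to +30\% of the centre value in `nDistance` equal steps and
#' `tracerdif` varied from -30\% to +10\% in `nTracerdif` equal steps
#' (capped at 1, its upper bound). All evaluations share one seed.
#'
#' @param center a [modelParams()] at the fitted optimum.
#' @param observed,config,widthFactor,stride,seed see [ssqObjective()].
#' @param nDistance,nTracerdif number of axis steps (defaults 12 and 8).
#' @return a [SensitivityGrid-class] object.
#' @export
sensitivityGrid <- function(center, observed, config, widthFactor = 10,
                            stride = 1L, seed = 1L,
                            nDistance = 12L, nTracerdif = 8L) {
  validObject(center)
  distVals <- center@distance * seq(0.7, 1.3, length.out = nDistance)
  tdVals <- pmin(center@tracerdif * seq(0.7, 1.1, length.out = nTracerdif), 1)
  m <- matrix(NA_real_, nrow = nDistance, ncol = nTracerdif)
  for (i in seq_len(nDistance)) {
    for (j in seq_len(nTracerdif)) {
      p <- replaceParams(center, c(distance = distVals[i], tracerdif = tdVals[j]))
      m[i, j] <- ssqObjective(p, observed, config, widthFactor,
                              seed = seed, stride = stride)
    }
  }
  k <- which.min(as.vector(t(m)))          # first minimum, row-major
  i <- (k - 1L) %/% ncol(m) + 1L
  j <- (k - 1L) %% ncol(m) + 1L
  new("SensitivityGrid", distanceValues = distVals, tracerdifValues = tdVals,
      objective = m, minIndex = c(i, j),
      minDistance = distVals[i], minTracerdif = tdVals[j])
}
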