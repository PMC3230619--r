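## Core lattice engine: active tracer displacement + passive mass-balance
## rebalancing. Layer 1 (R indexing) is the sediment-water interface; the
## user-facing convention is 0-based depth indices increasing downward.

#' Initialise the sediment lattice
#'
#' Builds the starting state: the `dLum` uppermost layers are completely
#' filled with tracer particles (the experimentally applied luminophore
#' layer), all deeper layers with non-marked sediment particles. Every layer
#' holds exactly `w` particles.
#'
#' @param config a [simConfig()].
#' @return a [latticeState()].
#' @examples
#' st <- initLattice(simConfig(d = 149, w = 2980, dLum = 20))
#' sum(tracerCounts(st)) # 59600
#' @export
initLattice <- function(config) {
  validObject(config)
  d <- config@d; w <- config@w; dLum <- config@dLum
  tracer <- integer(d)
  if (dLum > 0L) tracer[seq_len(dLum)] <- w
  latticeState(tracer = tracer, nonmarked = w - tracer, capacity = w)
}

## Displacement magnitudes with mean = distance, pluggable distribution.
## "fixed": integer part plus a Bernoulli fractional step, so the mean is
## still exactly `distance`.
drawMagnitudes <- function(n, distance, magnitudeDist = "poisson") {
  if (n == 0L) return(integer(0))
  switch(magnitudeDist,
    poisson   = rpois(n, distance),
    fixed     = {
      base <- floor(distance)
      frac <- distance - base
      as.integer(base) + (if (frac > 0) rbinom(n, 1L, frac) else 0L)
    },
    geometric = rgeom(n, 1 / (1 + distance)),
    stopUsage("unknown magnitude distribution '%s'", magnitudeDist))
}

## Second moment of the magnitude distribution, used by the diffusion-limit
## cross-checks: Poisson(l) has E[m^2] = l + l^2.
magnitudeSecondMoment <- function(distance, magnitudeDist = "poisson") {
  switch(magnitudeDist,
    poisson   = distance + distance^2,
    fixed     = {
      base <- floor(distance); frac <- distance - base
      (1 - frac) * base^2 + frac * (base + 1)^2
    },
    geometric = {
      p <- 1 / (1 + distance)
      q <- 1 - p
      q * (2 - p) / p^2          # E[m^2] of a count-of-failures geometric
    },
    stopUsage("unknown magnitude distribution '%s'", magnitudeDist))
}

#' Draw one round of active tracer displacement
#'
#' For every tracer particle within the active depth range
#' (layers `0 .. round(range * d) - 1`), an independent Bernoulli trial with
#' success probability `activity` decides whether it is displaced this step.
#' Each displaced particle draws a direction (down with probability
#' `downwards`) and a magnitude from the configured distribution with mean
#' `distance`; the target layer is clamped to the column (wall boundaries:
#' particles stop in the top or bottom layer rather than leaving the grid).
#'
#' @param state a [latticeState()].
#' @param params a [modelParams()].
#' @param config a [simConfig()].
#' @return a [displacementLedger()] of per-layer removals and additions.
#' @export
drawActiveDisplacements <- function(state, params, config) {
  d <- length(state@tracer)
  activeDepth <- min(d, as.integer(round(params@range * d)))
  removals <- integer(d)
  additions <- integer(d)
  if (activeDepth >= 1L && params@activity > 0) {
    nDisp <- rbinom(activeDepth, state@tracer[seq_len(activeDepth)],
                    params@activity)
    removals[seq_len(activeDepth)] <- nDisp
    total <- sum(nDisp)
    if (total > 0L) {
      src <- rep.int(seq_len(activeDepth), nDisp)      # 1-based source layers
      down <- runif(total) < params@downwards
      mag <- drawMagnitudes(total, params@distance, config@magnitudeDist)
      tgt <- src + ifelse(down, mag, -mag)
      tgt <- pmin.int(pmax.int(tgt, 1L), d)            # wall boundaries
      additions <- tabulate(tgt, nbins = d)
    }
  }
  displacementLedger(removals = removals, additions = additions)
}

#' Apply a displacement ledger to a lattice state
#'
#' Subtracts the recorded tracer removals and adds the recorded additions.
#' Total tracer is conserved; layer totals may temporarily deviate from the
#' capacity `w` until [passiveRebalance()] restores them.
#'
#' @param state a [latticeState()].
#' @param ledger a [displacementLedger()].
#' @return the updated [latticeState()].
#' @export
applyLedger <- function(state, ledger) {
  if (length(ledger@removals) != length(state@tracer))
    stopInternal("ledger length %d does not match lattice depth %d",
                 length(ledger@removals), length(state@tracer))
  if (any(ledger@removals > state@tracer))
    stopInternal("ledger removes more tracer than present in layer %d",
                 which(ledger@removals > state@tracer)[1] - 1L)
  state@tracer <- state@tracer - ledger@removals + ledger@additions
  state
}

## Number of tracer particles among `k` particles selected sequentially
## without replacement from a pool of `nTracer` tracers (weight `omega`) and
## `nOther` non-marked particles (weight 1), each draw proportional to the
## remaining weights (Wallenius-type urn). Implemented through the
## exponential-keys equivalence: the k smallest of Exp(1)/weight keys are
## exactly the sequentially selected items.
rWalleniusCount <- function(k, nTracer, nOther, omega) {
  if (k <= 0L || nTracer == 0L) return(0L)
  if (nOther == 0L) return(as.integer(min(k, nTracer)))
  keys <- c(rexp(nTracer) / omega, rexp(nOther))
  thr <- sort.int(keys, partial = k)[k]
  sum(keys[seq_len(nTracer)] <= thr)
}

## Reference implementation: literal one-particle-at-a-time selection. Kept
## for cross-checking the keys method in the test suite.
rWalleniusCountSequential <- function(k, nTracer, nOther, omega) {
  moved <- 0L
  for (i in seq_len(k)) {
    pTracer <- nTracer * omega / (nTracer * omega + nOther)
    if (runif(1) < pTracer) {
      nTracer <- nTracer - 1L
      moved <- moved + 1L
    } else {
      nOther <- nOther - 1L
    }
  }
  moved
}

#' Restore layer capacities by passive particle relocation
#'
#' After active displacement some layers exceed and some fall short of the
#' fixed capacity `w`. Starting from the bottom layer, the surplus of each
#' over-full layer is relocated to the layer above; the relocated particles
#' are drawn at random from all particles currently in the layer (including
#' ones just received from below), with tracer particles weighted by
#' `tracerdif` relative to non-marked particles. If the pass leaves a surplus
#' in the top layer, the procedure is inverted and surplus is pushed downward
#' from the top. On return every layer holds exactly `w` particles; tracer and
#' non-marked totals are unchanged.
#'
#' @param state a [latticeState()]; total particle count must equal `d * w`.
#' @param tracerdif tracer selection weight in (0, 1].
#' @return the rebalanced [latticeState()].
#' @export
passiveRebalance <- function(state, tracerdif = 1) {
  t <- state@tracer; s <- state@nonmarked
  w <- state@capacity; d <- length(t)
  if (sum(t) + sum(s) != d * w)
    stopInternal("global mass %d does not match d*w = %d", sum(t) + sum(s), d * w)
  if (tracerdif <= 0 || tracerdif > 1)
    stopUsage("'tracerdif' must be in (0, 1], got %g", tracerdif)
  if (d >= 2L) {
    for (i in d:2) {                     # upward pass, bottom layer first
      k <- t[i] + s[i] - w
      if (k > 0L) {
        mt <- rWalleniusCount(k, t[i], s[i], tracerdif)
        t[i] <- t[i] - mt;            s[i] <- s[i] - (k - mt)
        t[i - 1L] <- t[i - 1L] + mt;  s[i - 1L] <- s[i - 1L] + (k - mt)
      }
    }
    if (t[1] + s[1] > w) {               # inverted, downward pass
      for (i in 1:(d - 1L)) {
        k <- t[i] + s[i] - w
        if (k > 0L) {
          mt <- rWalleniusCount(k, t[i], s[i], tracerdif)
          t[i] <- t[i] - mt;            s[i] <- s[i] - (k - mt)
          t[i + 1L] <- t[i + 1L] + mt;  s[i + 1L] <- s[i + 1L] + (k - mt)
        }
      }
    }
  }
  if (any(t + s != w))
    stopInternal("rebalancing failed to restore layer capacities")
  state@tracer <- t; state@nonmarked <- s
  state
}

#' Advance the lattice by one time step
#'
#' One model step is the composition of the two model parts: a round of
#' active tracer displacement ([drawActiveDisplacements()] applied via
#' [applyLedger()]) followed by [passiveRebalance()]. All state invariants
#' (capacity, mass conservation) hold again on return.
#'
#' @inheritParams drawActiveDisplacements
#' @return the advanced [latticeState()].
#' @export
stepLattice <- function(state, params, config) {
  ledger <- drawActiveDisplacements(state, params, config)
  passiveRebalance(applyLedger(state, ledger), params@tracerdif)
}

#' Forward-simulate a tracer profile time series
#'
#' Initialises the lattice from `config`, runs `nSteps` model steps and
#' records the per-layer tracer counts after every step. Column 1 of the
#' result is the initial condition (time 0). If `config` carries a seed the
#' RNG is seeded before the run, making the output reproducible.
#'
#' @param params a [modelParams()].
#' @param config a [simConfig()].
#' @return a [profileSeries()] with `nSteps + 1` columns.
#' @examples
#' cfg <- simConfig(d = 30, w = 50, dLum = 5, nSteps = 10, seed = 1)
#' prof <- simulateProfile(modelParams(activity = 0.5, distance = 2), cfg)
#' colSums(profileCounts(prof)) # constant: tracer mass is conserved
#' @export
simulateProfile <- function(params, config) {
  validObject(params); validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  state <- initLattice(config)
  out <- matrix(0, nrow = config@d, ncol = config@nSteps + 1L)
  out[, 1L] <- state@tracer
  for (k in seq_len(config@nSteps)) {
    state <- stepLattice(state, params, config)
    out[, k + 1L] <- state@tracer
  }
  profileSeries(out, dtMin = config@dtMin, layerHeightMm = config@layerHeightMm)
}
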