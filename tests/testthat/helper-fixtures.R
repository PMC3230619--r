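## Shared fixtures: everything is generated in code, nothing on disk.

toyConfig <- function(d = 6, w = 10, dLum = 2, nSteps = 3, seed = NA,
                      ...) {
  simConfig(d = d, w = w, dLum = dLum, nSteps = nSteps, seed = seed, ...)
}

symParams <- function(activity = 0.5, distance = 1.5, tracerdif = 1,
                      downwards = 0.5, range = 1) {
  modelParams(activity = activity, distance = distance,
              downwards = downwards, range = range, tracerdif = tracerdif)
}

## A random valid post-step state: every layer total equals w.
randomBalancedState <- function(d, w) {
  tr <- sapply(seq_len(d), function(i) sample.int(w + 1L, 1L) - 1L)
  latticeState(tr, w - tr, w)
}

## A random unbalanced state with intact global mass d*w (for rebalance tests).
randomUnbalancedState <- function(d, w) {
  total <- d * w
  nTracer <- sample.int(total, 1L) - 1L
  ## spread particles over layers, then force global mass to d*w
  cuts <- sort(sample.int(total - 1L, d - 1L))
  perLayer <- diff(c(0L, cuts, total))
  tr <- vapply(seq_len(d), function(i) {
    if (perLayer[i] == 0L) 0L else rbinom(1L, perLayer[i], nTracer / total)
  }, integer(1))
  latticeState(tr, perLayer - tr, w)
}

tracerDepthVar <- function(state) {
  x <- rep(seq_along(tracerCounts(state)), tracerCounts(state))
  if (length(x) < 2) return(0)
  sum((x - mean(x))^2) / length(x)
}

## Truth and study-scale configurations used by the recovery harnesses:
## a 149-layer column, 20 tracer layers, 24 five-minute steps; observation at
## the full imaged width (2980), fitting at one tenth of it (298).
recoveryTruth <- function() {
  modelParams(activity = 0.674, distance = 4.242, downwards = 0.5,
              tracerdif = 0.929)
}
observationConfig <- function(seed) {
  simConfig(d = 149, w = 2980, dLum = 20, nSteps = 24, seed = seed)
}
fittingConfig <- function() {
  simConfig(d = 149, w = 298, dLum = 20, nSteps = 24)
}
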