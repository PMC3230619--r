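test_that("initLattice fills the tracer band and honours layer capacity", {
  st <- initLattice(simConfig(d = 149, w = 2980, dLum = 20))
  expect_equal(sum(tracerCounts(st)), 20 * 2980)
  expect_equal(tracerCounts(st)[1:20], rep(2980L, 20))
  expect_equal(tracerCounts(st)[21:149], rep(0L, 129))
  expect_true(all(tracerCounts(st) + nonmarkedCounts(st) == 2980L))

  empty <- initLattice(simConfig(d = 5, w = 10, dLum = 0))
  expect_equal(sum(tracerCounts(empty)), 0)
  expect_equal(nonmarkedCounts(empty), rep(10L, 5))

  full <- initLattice(simConfig(d = 3, w = 4, dLum = 3))
  expect_equal(sum(tracerCounts(full)), 12)
  expect_equal(sum(nonmarkedCounts(full)), 0)
})

test_that("invalid lattice geometry is rejected naming the offending field", {
  expect_error(simConfig(d = 0, w = 10, dLum = 0), "'d'")
  expect_error(simConfig(d = 5, w = 10, dLum = 7), "'dLum'")
  expect_error(simConfig(d = 5, w = 10, dLum = 2, dtMin = -1), "'dtMin'")
  expect_error(modelParams(activity = 1.2), "'activity'")
  expect_error(modelParams(tracerdif = 0), "'tracerdif'")
  expect_error(modelParams(distance = -1), "'distance'")
})

test_that("zero activity draws an empty displacement ledger", {
  set.seed(1)
  st <- randomBalancedState(8, 12)
  led <- drawActiveDisplacements(st, symParams(activity = 0), toyConfig(d = 8, w = 12))
  expect_equal(sum(led@removals), 0)
  expect_equal(sum(led@additions), 0)
})

test_that("a deterministic displacement moves the single tracer as prescribed", {
  ## one tracer in layer index 1 (0-based), certain displacement, fixed
  ## magnitude 2, downward for sure -> lands in layer index 3
  st <- latticeState(c(0L, 1L, 0L, 0L, 0L), c(5L, 4L, 5L, 5L, 5L), 5L)
  par <- modelParams(activity = 1, distance = 2, downwards = 1, tracerdif = 1)
  cfg <- simConfig(d = 5, w = 5, dLum = 0, magnitudeDist = "fixed")
  set.seed(2)
  led <- drawActiveDisplacements(st, par, cfg)
  expect_equal(led@removals, c(0L, 1L, 0L, 0L, 0L))
  expect_equal(led@additions, c(0L, 0L, 0L, 1L, 0L))
})

test_that("displacement counts follow the binomial law", {
  set.seed(3)
  cfg <- toyConfig(d = 5, w = 20, dLum = 1, nSteps = 1)
  st <- initLattice(cfg)
  par <- symParams(activity = 0.5)
  draws <- replicate(10000, sum(drawActiveDisplacements(st, par, cfg)@removals))
  n <- 20; p <- 0.5
  seMean <- sqrt(n * p * (1 - p) / 10000)
  expect_lt(abs(mean(draws) - n * p), 3 * seMean)
  seVar <- n * p * (1 - p) * sqrt(2 / 9999)
  expect_lt(abs(var(draws) - n * p * (1 - p)), 3 * seVar)
})

test_that("magnitude distributions have the configured mean", {
  set.seed(4)
  for (dist in c("poisson", "fixed", "geometric")) {
    m <- bioturb:::drawMagnitudes(20000, 2.3, dist)
    expect_true(all(m >= 0))
    expect_lt(abs(mean(m) - 2.3) / 2.3, 0.05)
  }
  ## fixed distribution only takes the two neighbouring integers
  m <- bioturb:::drawMagnitudes(1000, 2.3, "fixed")
  expect_true(all(m %in% c(2L, 3L)))
})

test_that("applyLedger conserves tracer and reports impossible removals", {
  st <- randomBalancedState(6, 10)
  d <- 6
  expect_identical(applyLedger(st, displacementLedger(integer(d), integer(d))), st)

  st2 <- latticeState(c(5L, 0L, 0L, 0L, 0L, 5L), c(5L, 10L, 10L, 10L, 10L, 5L), 10L)
  led <- displacementLedger(c(3L, 0L, 0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L, 0L, 3L))
  out <- applyLedger(st2, led)
  expect_equal(sum(tracerCounts(out)), sum(tracerCounts(st2)))
  expect_equal(tracerCounts(out)[1] + nonmarkedCounts(out)[1], 7)
  expect_equal(tracerCounts(out)[6] + nonmarkedCounts(out)[6], 13)

  bad <- displacementLedger(c(6L, 0L, 0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L, 0L, 6L))
  expect_error(applyLedger(st2, bad), "more tracer than present")

  set.seed(5)
  for (i in 1:1000) {
    st <- randomBalancedState(6, 10)
    rem <- vapply(tracerCounts(st), function(t)
      if (t > 0L) sample.int(t + 1L, 1L) - 1L else 0L, integer(1))
    add <- tabulate(sample.int(6, sum(rem), replace = TRUE), 6)
    out <- applyLedger(st, displacementLedger(rem, add))
    expect_identical(sum(tracerCounts(out)), sum(tracerCounts(st)))
  }
})

test_that("passiveRebalance restores every layer to capacity", {
  balanced <- randomBalancedState(7, 9)
  expect_identical(passiveRebalance(balanced, 0.8)@tracer, balanced@tracer)

  ## surplus at the bottom, deficits spread above
  st <- latticeState(c(0L, 0L, 0L, 8L), c(3L, 4L, 3L, 2L), 5L)
  out <- passiveRebalance(st, 1)
  expect_true(all(tracerCounts(out) + nonmarkedCounts(out) == 5L))
  expect_equal(sum(tracerCounts(out)), 8)

  ## global mass mismatch is an internal error
  expect_error(passiveRebalance(latticeState(c(1L, 0L), c(1L, 1L), 5L), 1),
               "global mass")
})

test_that("unweighted rebalance composition is hypergeometric", {
  ## layer with 5 tracer + 7 non-marked and surplus 2, receiving layer empty:
  ## the pair moved up must be hypergeometric at tracerdif = 1
  set.seed(6)
  nrep <- 4000
  moved <- integer(nrep)
  for (r in seq_len(nrep)) {
    st <- latticeState(c(0L, 5L), c(8L, 7L), 10L)
    moved[r] <- tracerCounts(passiveRebalance(st, 1))[1]
  }
  obs <- tabulate(moved + 1L, 3)
  p <- dhyper(0:2, 5, 7, 2)
  chi <- sum((obs - nrep * p)^2 / (nrep * p))
  expect_lt(chi, qchisq(0.999, df = 2))
})

test_that("weighted selection matches a literal sequential sampler", {
  ## dual route: exponential-keys draw vs one-particle-at-a-time selection
  set.seed(7)
  a <- replicate(4000, bioturb:::rWalleniusCount(4L, 6L, 6L, 0.5))
  b <- replicate(4000, bioturb:::rWalleniusCountSequential(4L, 6L, 6L, 0.5))
  tab <- rbind(tabulate(a + 1L, 5), tabulate(b + 1L, 5))
  keep <- colSums(tab) > 10
  p <- suppressWarnings(stats::chisq.test(tab[, keep]))$p.value
  expect_gt(p, 0.001)
})

test_that("a model step conserves mass and restores capacity", {
  set.seed(8)
  cfg <- toyConfig(d = 10, w = 15, dLum = 3, nSteps = 1)
  st <- initLattice(cfg)
  par <- symParams(activity = 0.7, distance = 2, tracerdif = 0.8)
  for (i in 1:20) {
    st <- stepLattice(st, par, cfg)
    expect_equal(sum(tracerCounts(st)), 3 * 15)
    expect_true(all(tracerCounts(st) + nonmarkedCounts(st) == 15L))
  }
})

test_that("zero activity is a fixed point of the dynamics", {
  cfg <- toyConfig(d = 8, w = 12, dLum = 2, nSteps = 10, seed = 9)
  prof <- simulateProfile(symParams(activity = 0), cfg)
  m <- profileCounts(prof)
  expect_true(all(m == m[, 1]))
})

test_that("depth variance grows at the random-walk rate for dilute tracer", {
  ## dilute mid-column band keeps the passive return flow essentially
  ## tracer-free, so variance must grow by activity * E[m^2] per step
  set.seed(10)
  d <- 101; w <- 200
  tr <- integer(d); tr[51] <- 20L
  par <- symParams(activity = 0.5, distance = 1.5)
  cfg <- simConfig(d = d, w = w, dLum = 0, nSteps = 1)
  nrep <- 200; nstep <- 5
  vend <- numeric(nrep)
  for (r in seq_len(nrep)) {
    st <- latticeState(tr, rep(w, d) - tr, w)
    for (k in seq_len(nstep)) st <- stepLattice(st, par, cfg)
    vend[r] <- tracerDepthVar(st)
  }
  rate <- mean(vend) / nstep
  expected <- 0.5 * bioturb:::magnitudeSecondMoment(1.5, "poisson")
  expect_lt(abs(rate - expected) / expected, 0.10)
})

test_that("wall boundaries trap tracer at the bottom under pure downward motion", {
  cfg <- simConfig(d = 6, w = 8, dLum = 2, nSteps = 60, seed = 11)
  par <- modelParams(activity = 0.9, distance = 3, downwards = 1, tracerdif = 1)
  prof <- simulateProfile(par, cfg)
  m <- profileCounts(prof)
  expect_true(all(colSums(m) == 16))          # nothing ever leaves the grid
  expect_equal(m[6, 61], 8)                   # bottom layer saturated
  expect_gte(sum(m[5:6, 61]), sum(m[5:6, 1])) # tracer accumulated at depth
})

test_that("no active removal originates below the range limit", {
  set.seed(12)
  cfg <- toyConfig(d = 10, w = 10, dLum = 10, nSteps = 1)
  st <- initLattice(cfg)  # tracer everywhere
  par <- symParams(activity = 1, distance = 2, range = 0.5)
  for (i in 1:50) {
    led <- drawActiveDisplacements(st, par, cfg)
    expect_true(all(led@removals[6:10] == 0L))
    expect_gt(sum(led@removals[1:5]), 0L)
  }
})

test_that("simulateProfile is shape-correct, conservative and seed-reproducible", {
  cfg0 <- toyConfig(d = 5, w = 6, dLum = 1, nSteps = 0, seed = 1)
  prof0 <- simulateProfile(symParams(), cfg0)
  expect_equal(dim(profileCounts(prof0)), c(5, 1))

  cfg <- simConfig(d = 149, w = 298, dLum = 20, nSteps = 24, seed = 13)
  par <- recoveryTruth()
  prof <- simulateProfile(par, cfg)
  expect_equal(dim(profileCounts(prof)), c(149, 25))
  expect_true(all(colSums(profileCounts(prof)) == 5960))

  again <- simulateProfile(par, cfg)
  expect_identical(profileCounts(prof), profileCounts(again))
  cfg@seed <- 14L
  other <- simulateProfile(par, cfg)
  expect_false(identical(profileCounts(prof), profileCounts(other)))
})
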