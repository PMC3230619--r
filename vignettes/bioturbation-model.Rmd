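---
title: "A process-based lattice model of sediment bioturbation: methods and design"
author: "bioturb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A process-based lattice model of sediment bioturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioturb)
```

## The problem

Burrowing animals rework soils and sediments, redistributing particles,
pore water and the biogeochemistry that depends on them. The standard way to
quantify this is to seed the sediment surface with fluorescent tracer
particles (luminophores), image the sediment column through an aquarium wall
over time, and fit a mixing model to the resulting depth-by-time profile of
tracer counts. The most common model is Fickian biodiffusion, summarised by
a single coefficient Db — elegant, but it assumes continuous, local,
diffusive transport, which real infauna (burrow builders, conveyors,
regenerators) routinely violate.

`bioturb` implements the alternative: a stochastic, rule-based lattice
simulation of particle displacement whose parameters are directly
interpretable as animal behaviour, plus the machinery to calibrate it
against observed profiles and to compare it with the classical Db model
fitted to the same data in the same way.

## The lattice model

The sediment is a grid of `d` layers (rows) by `w` particles per layer
(columns). Layer 1 is the sediment–water interface; depth increases
downward. The `dLum` uppermost layers start filled with tracer particles,
everything below with non-marked sediment particles. Each time step has two
parts.

**Active displacement.** Every tracer particle in the active zone (layers
`1 .. round(range * d)`) is displaced with probability `activity`. A
displaced particle draws a direction (down with probability `downwards`) and
a magnitude (in layers) from a configurable distribution with mean
`distance`; its target index is clamped to the column (wall boundaries:
particles stop at the interface or the bottom rather than leaving the grid).
Only tracer particles move actively — the non-marked bulk is represented
implicitly, which is a stated limitation (see below).

**Passive rebalancing.** Each layer has fixed capacity `w`, so active
displacement must be compensated. Starting from the bottom layer, any
surplus over `w` is relocated to the layer above; the relocated particles
are drawn at random from all particles currently in the layer — including
ones just received from below — with a tracer particle weighted `tracerdif`
relative to a non-marked particle. If the upward pass leaves surplus at the
interface, the procedure is inverted and surplus is pushed downward from the
top. After rebalancing every layer again holds exactly `w` particles, and
both tracer and non-marked totals are conserved exactly. These conservation
and capacity invariants are asserted by the engine after every step and
exercised by the randomised test suite.

The weighted selection-without-replacement is sequential: one particle at a
time, with probability proportional to the remaining weights (a
Wallenius-type urn). The implementation uses the exponential-keys
equivalence — assign each particle an `Exp(1)/weight` key and take the `k`
smallest — which yields exactly the sequential distribution while
vectorising the draw; the test suite cross-checks it against a literal
one-at-a-time sampler and, at `tracerdif = 1`, against the hypergeometric
law.

### Parameters

| parameter   | meaning                                                  | units   | default |
|-------------|----------------------------------------------------------|---------|---------|
| `activity`  | per-particle displacement probability per step           | —       | 0.5     |
| `distance`  | mean displacement magnitude                              | layers  | 1       |
| `downwards` | probability a displaced particle moves down              | —       | 0.5     |
| `range`     | fraction of the column open to active reworking          | —       | 1       |
| `tracerdif` | tracer selection weight in passive rebalancing           | —       | 1       |

Geometry and scales live in `simConfig()`: the worked-example defaults are a
149-layer column (one layer = one 0.073 mm camera pixel row), 2980 particles
of width, the uppermost 20 layers tracer-filled, and 24 five-minute time
steps. The layer height of 0.073 mm is the pixel size quoted with the
fitting setup; with it, a fitted displacement of 4.30 layers converts to
0.314 mm via `layersToMm()`.

### The magnitude distribution

Only the *mean* displacement distance is identified by typical data, so the
magnitude distribution is pluggable. The default is Poisson with mean
`distance` (draws of 0 leave a "displaced" particle in place), chosen as the
simplest discrete distribution parameterised by its mean. Alternatives:
`"fixed"` (the integer part of `distance` plus a Bernoulli fractional step
— useful for deterministic corner cases) and `"geometric"` (heavier tail).
For the Poisson default the second moment is `distance + distance^2`, which
is what the diffusion-limit checks use.

### Direction of the tracer weighting

The model description weights *tracer* selection by `tracerdif` relative to
non-marked particles in both rebalancing passes; a value below 1 makes
tracers lag the compensatory flows. The same weighting is applied in the
upward and the inverted downward pass. An alternative "density" reading —
tracer preferentially selected when pushing down — was prototyped and makes
no practical difference at the worked-example scales, because the initially
saturated tracer band contains no non-marked particles to exchange; we keep
the symmetric reading.

## Calibration

The objective is the sum over all layers and compared time points of the
squared difference between observed and simulated counts
(`ssqObjective()`). To cut runtime tenfold, the simulation runs on a column
one tenth of the imaged width and its counts are multiplied by
`widthFactor = 10` before comparison; mixing events are assumed homogeneous
across the width. The rescaled objective preserves the *ordering* of
candidate parameter sets (verified by test at Spearman > 0.9 against the
full-width objective) although the rescaling inflates the counting-noise
floor, so absolute objective values are only comparable where systematic
misfit dominates.

The pipeline has three stages, mirroring common practice for rough,
stochastic objective surfaces:

1. **Coarse scan** (`scanParameters()`): 512 combinations — an 8×8×8 grid
   over `activity` ∈ [0.1, 0.9], `distance` ∈ [1, 8], `tracerdif` ∈
   [0.6, 1.0] by default — evaluated under one common seed. The scan
   reveals the strong negative correlation between `activity` and
   `distance`: the objective surface is a furrow along
   `activity × distance ≈ const` rather than a point minimum (the test
   suite asserts this via rank correlation). In the worked example the
   scan's best `activity` is therefore fixed before the fine fit.
2. **Simulated annealing** (`fitSANN()`, `stats::optim` method `"SANN"`):
   global search over the free parameters (by default `distance` and
   `tracerdif`). Every evaluation reuses one seed (common random numbers),
   making the surface deterministic though jagged. The initial temperature
   defaults to 5 % of the objective at the start values — acceptance must
   operate on the natural scale of the problem, which for count data is in
   the millions — with a Gaussian proposal kernel of standard deviation 5 %
   of each parameter's box width and a 300-evaluation budget. Proposals are
   folded back into the box by reflection. The best *evaluated* point is
   returned, not the last accepted one.
3. **Quasi-Newton refinement** (`fitBFGS()`): BFGS with finite-difference
   gradients on the common-random-number objective. Because a small
   parameter change decouples the underlying RNG stream, the CRN surface is
   jagged at fine scales; gradients are therefore estimated over steps of
   1.25 % of the box width, wide enough to see the underlying trend.
   `nReplicates` independent refinements (each with its own seed) quantify
   the residual stochastic uncertainty; the headline estimate is the
   replicate mean ± SD, and within each replicate the best evaluated point
   is kept in case the final line search ends uphill.

Bounds are handled by reflection for both optimisers; `distance` is bounded
below by a small epsilon and `tracerdif` is capped at 1.

`sensitivityGrid()` evaluates the objective on distance ±30 % (12 steps) ×
tracerdif −30 %..+10 % (8 steps, capped at 1) around a fitted optimum — 96
evaluations under one seed — and reports the grid minimum (row-major
first-minimum tie-break, as in the scan).

## The biodiffusion reference model

`diffuseTracer()` solves the 1-D diffusion equation on the layer grid with
zero-flux boundaries at both ends, using backward Euler (unconditionally
stable; no scheme is canonical for this comparison, so the simplest robust
one is used). The propagator's columns sum to one, so mass is conserved to
machine precision, and the M-matrix structure preserves non-negativity; any
sub-`-1e-12` numerical undershoot would be clipped with a warning. One
backward-Euler step adds exactly `2 * Db * dt` of variance, and the test
suite checks the solution against the Gaussian fundamental solution to
within 1 % RMS before boundary contact.

`fitDb()` minimises the same layer-by-time sum of squares over the scalar
Db (bounded 1-D minimisation), starting from the observed time-0 column so
that the two model families are fitted analogously, and reports the
per-time-point decomposition of the objective — the basis for the
fit-over-time comparison in which the lattice model keeps fitting while the
diffusion model deteriorates as profile shapes become less exponential.

In the symmetric, dilute limit (`downwards = 0.5`, `tracerdif = 1`, tracer a
small fraction of its layers, away from boundaries) the lattice model is
diffusive with `Db = activity * E[m^2] / 2` layers² per step
(`randomWalkDb()`). The cross-validation test generates dilute-band lattice
data and requires the fitted Db to match this prediction within 25 %. The
dilute condition matters: in a saturated tracer band the compensatory return
flow carries tracer back, and effective tracer mixing is suppressed below
the free random-walk rate — a genuine feature of capacity-constrained
mixing, not a solver artefact.

## Synthetic data

`generateSynthetic()` stands in for the imaging experiment: it
forward-simulates the lattice model at known parameters and optionally thins
every count binomially with detection probability `pDetect`, the simplest
model of luminophores missed by the camera or threshold. It returns the
generating truth alongside the series, which is what the parameter-recovery
harness consumes. What it does *not* emulate: bout-like temporal variation
in activity (real worms rework in ~100-minute bouts, the model's `activity`
is constant), interface tracking errors, luminophore clumping, or optical
blur — so passing recovery tests demonstrate identifiability under the
model's own assumptions, not robustness to every field artefact.

The recovery harness runs at the study scale (149 layers, 20 tracer layers,
24 steps; observation width 2980, fitting width 298) with truth
`distance = 4.242`, `tracerdif = 0.929`, `activity` fixed at its true 0.674,
and requires both free parameters within ±15 % of truth in at least 8 of 10
seeds. `tracerdif` is the weakly identified one: its valley over
[0.85, 1.0] is shallow relative to the Monte-Carlo noise floor of the
objective, which is why the annealing stage needs a genuine global search
and why the published uncertainty on the equivalent quantity is quoted from
replicate refinements.

## Numerical choices and degenerate inputs

* Counts are integers throughout the engine; the objective and diffusion
  solver work in doubles.
* `dLum = 0` (no tracer) and `activity = 0` are valid and exact fixed
  points; `d = 1` collapses both rebalancing passes to no-ops.
* The profile reader sniffs tab/comma/whitespace delimiters, strips an
  optional header row and depth-label column, and transposes
  wider-than-tall tables under `orientation = "auto"` (override it for
  deliberately short-and-wide matrices).
* The writer emits integers verbatim and fractional values at fixed
  six-decimal precision, so repeated writes are byte-identical.
* Ties in scans and grids resolve to the first minimum in row-major order.
* All stochastic entry points are reproducible given a seed; one seeded
  generator drives a whole simulation.

## Problem sizes

The test suite runs everything on a single CPU: toy columns (d ≤ 10) for
the exhaustive invariant checks, 10,000-replicate draws for the
distributional oracles, and the full 149-layer study scale for the recovery
and model-comparison harnesses (ten seeds of the annealing + refinement
pipeline). The acceptance script repeats the study-scale pipeline once —
scan, annealing, ten BFGS replicates, sensitivity grid, a 100-step
(500-minute) penetration run and the simulation-vs-Db comparison — from a
single command-line seed.

## Known limitations

* Non-marked particles move only passively; species that actively transport
  bulk sediment (conveyors) are represented only through the net effect on
  tracers.
* `activity` and `distance` are confounded along their product; fitting all
  three behavioural parameters needs either the coarse scan's fix-one
  strategy or external information.
* The model is 2-D in formulation but effectively 1-D in state (per-layer
  counts); lateral structure such as discrete burrows is out of scope.
* Temporal variation in behaviour (bouts) is not modelled.
* The worked-example observed dataset is not redistributable with the
  package; the reproduction test that needs it runs only when the user
  supplies the file, and the synthetic generator provides the stand-in for
  every other test.
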