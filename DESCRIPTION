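Package: bioturb
Title: Process-Based Lattice Simulation and Calibration of Sediment Bioturbation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A stochastic, spatially explicit (2D) lattice model of particle
    reworking by sediment infauna. Active displacement of luminophore tracer
    particles is simulated as a constrained random walk and followed by a
    mass-balance passive rebalancing step that restores the fixed capacity of
    every sediment layer, optionally weighting tracer against non-marked
    particles. The package fits the behavioural parameters (activity, mean
    displacement distance, tracer weighting) to observed depth-by-time tracer
    profiles by sum-of-squares minimisation (coarse parameter scan, simulated
    annealing, then quasi-Newton refinement with replicates), provides a
    sensitivity grid around the optimum, and fits a classical biodiffusion
    (Db) reference model for comparison. Plain-text profile readers/writers, a
    synthetic-data generator with binomial detection noise, and a command-line
    interface complete the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'lattice.R'
    'calibration.R'
    'diffusion.R'
    'io.R'
    'show-methods.R'
    'cli.R'
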