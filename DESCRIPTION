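Package: memperm
Title: Membrane Permeation Free-Energy Workflows from Biased Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for computing membrane permeation energetics and
    permeability coefficients from adaptively biased trajectories.
    Implements well-tempered metadynamics bias deposition with on-the-fly
    c(t) reweighting, free-energy surface reconstruction with three-block
    error estimation, symmetrization and asymmetry checks, string-method
    minimum free-energy paths on two-dimensional surfaces, pKa-based
    combination of protomer surfaces, position-dependent diffusion
    estimation from restrained trajectories, and the inhomogeneous
    solubility-diffusion permeability model. Ships an overdamped Langevin
    sampler on analytic model membrane landscapes so the whole pipeline is
    testable at desk scale, and reads/writes PLUMED-dialect COLVAR, HILLS
    and grid text formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
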