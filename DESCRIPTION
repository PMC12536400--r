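Package: permeakit
Title: Membrane Permeability of Ionizable Multi-Tautomer Permeants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes membrane permeability of ionizable, multi-tautomer
    permeants from one-dimensional free-energy and diffusivity profiles via
    the inhomogeneous solubility-diffusion (ISD) model.  Provides microstate
    and macrostate equilibrium populations from macroscopic and microscopic
    acid-dissociation constants, effective-permeability protocols
    (pH-partitioning and Boltzmann-weighted average potential), kinetic-regime
    checks for liposomal fluorescence assays, a position-dependent diffusivity
    estimator for one-dimensional trajectories, and a synthetic-data generator
    (W-shaped permeation profiles, overdamped Langevin trajectories,
    ionization schemes) with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
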