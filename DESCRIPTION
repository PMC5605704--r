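Package: crowdring
Title: Coarse-Grained Ring-Polymer Simulations in Crowded Cylindrical Confinement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Langevin-dynamics engine and analysis pipeline for a bead-spring
    (WCA/FENE) ring polymer confined to a cylinder together with explicit
    spherical crowders, a minimal physical model of the two arms of a circular
    bacterial chromosome in the nucleoid. Provides pair and wall interaction
    kernels with a cell-list production path and a brute-force oracle, system
    builders (helical ring initialization, random crowder packing with an
    inflation protocol at high volume fraction), a velocity-Verlet Langevin
    integrator with longitudinal periodic or capped boundaries, trajectory I/O
    in extended XYZ, chain-size and arm-organization observables (longitudinal
    span, mean-squared rescaled radial position, opposing-arm angular
    correlation, projected transverse density), an organization-state
    classifier, and orchestration for replicate ensembles and parameter sweeps
    over crowder volume fraction and monomer-wall interaction strength.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
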