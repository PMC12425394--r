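Package: cortarray
Title: Event-Driven Simulation of the Plant Cortical Microtubule Array
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic, event-driven simulation of cortical microtubule
    arrays on planar periodic domains, capped cylinders and boxes.
    Microtubules undergo dynamic instability with minus-end treadmilling
    and angle-dependent collision resolution (zippering, induced
    catastrophe, crossover). Three nucleation modes are provided:
    isotropic (ISO), global density-dependent microtubule-based
    nucleation (GDD), and a local density-dependent (LDD) algorithm that
    approximates membrane exploration of nucleation complexes by
    meta-trajectories, avoiding the inhomogeneity problem of naive
    microtubule-based nucleation. Includes the observable suite used to
    quantify array homogeneity, alignment and orientation (planar and
    surface-corrected nematic order parameters, orientation
    classification, axial density profiles, the control parameter G and
    octant projections), preset in-silico experiments, and brute-force
    reference engines for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
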