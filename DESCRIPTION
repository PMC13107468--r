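Package: pistack
Title: Orbital-Pair Decomposition of Exchange Repulsion in Pi-Stacked Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes and partitions the exchange (Pauli) repulsion between two
    closed-shell planar molecules in slip-stacked arrangements into occupied
    molecular orbital-pair contributions (MOPCE), groups them into pi-pi,
    pi-sigma and sigma-sigma classes and into symmetric/antisymmetric pi
    classes with respect to the long-axis mirror plane, scans cross-monomer
    orbital overlaps over in-plane displacements, and compares the resulting
    oscillatory structure with a closed-form particle-in-a-box overlap model.
    Ships a self-contained Gaussian-integral and restricted Hartree-Fock
    engine (McMurchie-Davidson recurrences, optional density fitting) together
    with independent brute-force oracles for validation on small fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
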