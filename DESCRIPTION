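Package: ionpmf
Title: Ion-Mediated Potentials of Mean Force Between Charged Nanospheres
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes and compares potentials of mean force (PMFs) between
    two oppositely charged nanospheres in symmetric 1:1 and 2:2 electrolytes
    by two routes: canonical Metropolis Monte Carlo of the primitive model
    with a pseudo-spring constraint-force estimator, and a nonlinear
    Poisson-Boltzmann finite-difference solver with multi-level grid
    focusing and free-energy evaluation.  Includes net bound-ion charge
    profiles, equivalent-salt mapping, charge-density landscapes, and the
    deviation statistics that quantify where the mean-field description
    breaks down.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
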