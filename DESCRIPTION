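Package: ompath
Title: Trajectories from the Principle of Least Action via Onsager-Machlup
    Minimization
Version: 0.1.0
Authors@R:
    person("Path", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Solves atomistic boundary-value problems by representing a
    trajectory Q(t) with a small neural network of time and training it to
    minimize the discretized Onsager-Machlup action subject to
    boundary-condition and energy-conservation penalties.  Includes a
    reduced-unit Lennard-Jones force field (free clusters and periodic
    liquids), a velocity-Verlet molecular-dynamics engine that provides
    ground-truth trajectories and endpoint fixtures, NADAM training with
    random-search selection of penalty weights, basin hopping and quenching
    for Lennard-Jones cluster minima, transition-path profiles with barrier
    and arc-length metrics, and liquid-state observables (radial
    distribution function, velocity autocorrelation, per-frame RMSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
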