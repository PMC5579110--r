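Package: chcsurf
Title: Stochastic Cahn-Hilliard-Cook Phase Segregation on Implicit Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates conserved phase separation and coarsening of a
    two-component field confined to a static curved surface, using the
    closest point method on a Cartesian narrow band around an implicit
    (signed-distance) geometry.  Supports deterministic Cahn-Hilliard
    dynamics and the stochastic Cahn-Hilliard-Cook extension with
    conserved Gaussian noise, constant and degenerate mobilities, a
    semi-implicit BDF2 time integrator with Schur-complement
    preconditioned flexible GMRES, and a mass-conserving global
    correction.  Includes coarsening diagnostics (characteristic length,
    energy, domain counts), ensemble growth-rate statistics with
    lognormal fits, and flat periodic reference solvers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
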