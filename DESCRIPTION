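Package: popmech
Title: Population Mechanics Models of T Cell Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of inertial ("population mechanics")
    models of T cell homeostasis, in which cell populations behave as damped
    elastic systems driven by homeostatic forces exerted by interleukins
    (IL-7, IL-15). Provides second-order ODE models of single populations,
    of clones competing for a shared interleukin, of the naive pool under
    antigenic forcing, and of naive/memory compartments competing for two
    interleukins; their closed-form equilibria, emergent carrying capacities
    (K = phi/mu) and linear stability analysis (ck > lambda*mu); the
    discrete calculus of memory clone turnover after activation events,
    with extinction predicates; affinity-based peripheral selection in the
    naive pool; and the classical Lotka-Volterra competition model as a
    contrast class. Constrained trajectories are integrated with event
    detection so that cell numbers and interleukin amounts never become
    negative.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
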