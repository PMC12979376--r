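Package: glvflux
Title: Biomass-Constrained Generalized Lotka-Volterra Dynamics with
    Trophic Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of generalized Lotka-Volterra (GLV)
    community dynamics under an explicit biomass budget.  Provides
    positivity-preserving integration in log-abundance coordinates,
    trophic functionals weighted by history (memory) measures or by the
    memory-free Dirac measure, abiotic-reservoir and energy-flux
    accounting with sign-scenario classification, a Picard-iteration
    check for the associated Volterra integral equation, harmonicity
    constraints on the effective trophic potential with their conic
    classification in two dimensions, and phase-portrait tools (Poincare
    period detection, orbit classification, cycle averages).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
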