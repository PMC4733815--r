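Package: wcdyn
Title: Wilson-Cowan Neural Population Dynamics Across Description Levels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of excitatory-inhibitory neural
    population dynamics at three levels of description: deterministic
    Wilson-Cowan mean-field equations with phase-plane, fixed-point and
    bifurcation analysis; spatially extended neural fields on 1-D and 2-D
    lattices with exponential connectivity kernels and wave metrology; and
    the exact stochastic master equation simulated with the Gillespie
    algorithm, together with its linear-noise (system-size) approximation.
    Companion statistical tools extract neuronal avalanches from event
    rasters, fit power-law and geometric size distributions, simulate
    critical branching processes, estimate Lorentzian power spectra, and
    measure pair correlations as a function of distance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
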