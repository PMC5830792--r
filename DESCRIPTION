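Package: mixsis
Title: Mixing and Diffusion in Two-Group Contagion Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the mixing level between two groups with
    different contagion propensities shapes equilibrium diffusion. Implements
    the mean-field two-type susceptible-infected-susceptible (SIS) model with
    an assortativity parameter m, closed-form epidemic thresholds and endpoint
    equilibria, numerical endemic-equilibrium curves over m, classification of
    the effective-adoption-rate plane into qualitative regimes, detection of
    Pareto-inefficient mixing levels, a generalized contagion model with
    state-conditional adoption and recovery rates, and a finite-population
    stochastic simulator whose mean dynamic the ODE system approximates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
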