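Package: agekin
Title: Kinetic Theory of Age-Structured Stochastic Birth, Death and Fission
    Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact event-driven simulation and deterministic solvers for
    stochastic age-structured populations undergoing budding birth, binary
    fission and death, with optional spatial diffusion.  Provides hazard-based
    model definitions, statistically exact non-Markovian samplers (inversion of
    the integrated hazard and Ogata-style thinning), McKendrick-von Foerster
    solvers by characteristics, Volterra renewal equations for the fecundity,
    factorial-moment fields obeying a generalized McKendrick-von Foerster
    equation, mean-field singlet/doublet theory for fission-death processes,
    Bellman-Harris renewal means, Gamma-distributed fission-time closed forms
    via contour integrals, numerical Laplace inversion (fixed Talbot and
    Gaver-Stehfest), and a master-equation oracle for age-independent rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
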