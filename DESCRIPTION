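Package: vaxgame
Title: Vaccination Games, Behavioural Epidemics, and the Price of Anarchy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying voluntary vaccination as an evolutionary game
    coupled to epidemic dynamics. Provides a spatial individual-based Monte
    Carlo epidemic simulator with diffusion, contact infection, incubation,
    mortality and waning infection- and vaccine-derived immunity; closed-form
    vaccination-game analysis (critical coverage, evolutionarily stable
    vaccination probability, endemic equilibria, regime classification); the
    SIR-with-vaccination ordinary differential equations in dimensional and
    nondimensional form; a five-compartment behavioural SIR model coupled to
    Fermi-rule strategy imitation; and the price-of-anarchy diagnostic that
    compares peak infection under selfish (Nash) and cooperative
    (system-optimal) vaccination dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
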