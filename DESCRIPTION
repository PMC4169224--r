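Package: adsim
Title: Stochastic Simulation of Anaerobic Digestion Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the anaerobic digestion reaction cascade (glucose
    fermentation, acetogenesis and the two methanogenic routes) as a
    discrete-event stochastic process. Five Monod-kinetics degradation
    reactions with fractional product stoichiometry are simulated with the
    Gillespie direct method and the explicit tau-leap method (Poisson firing
    counts), cross-validated against a deterministic ODE reference sharing
    the same rate kernel. Includes ensemble summaries, stochastic-versus-
    deterministic comparison metrics, stoichiometric cascade accounting and
    methane pathway attribution, plus YAML/JSON network configuration and
    CSV trajectory output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
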