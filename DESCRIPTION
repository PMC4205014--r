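Package: phoscycle
Title: Steady-State Analysis of Phosphorylation-Dephosphorylation Cycles
    with Enzyme Sequestration
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic modelling of covalent modification cycles in which a
    substrate protein is phosphorylated by a kinase and dephosphorylated by a
    phosphatase. Unlike the classical Goldbeter-Koshland approximation, the
    steady state retains the enzyme-substrate complexes, yielding a cubic
    equation with a unique admissible real root that is solved in closed form
    and cross-checked against a bracketed root finder and an implicit ODE
    integrator. Single-site solutions extend to n independent, identical
    phosphorylation sites through a binomial phosphoform distribution.
    Includes bundled STAT3 (JAK/SHP-1, one site) and IRF-5 (TBK-1/alkaline
    phosphatase, six sites) sweep scenarios, Michaelis-constant recovery from
    measured steady states, seeded fixture generation, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
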