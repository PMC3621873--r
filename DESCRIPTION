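Package: socvax
Title: Social Influence and Cost Minimization in Vaccination Decision Making
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates voluntary vaccination decision making on a weighted
    social contact network. Each individual combines a game-theoretic
    cost-minimized choice, driven by the perceived infection risk among
    unvaccinated neighbours, with a social opinion formed under social impact
    theory and a Fermi (logistic) comparison of the influence strengths of the
    two camps; a conformity rate sets how often the social opinion overrides
    the cost-based choice. Steady-state vaccination coverage feeds a
    homogeneous-mixing SIR model to obtain epidemic attack rates and
    herd-immunity thresholds. Includes a calibrated synthetic generator for
    dense, clustered school-type contact networks, Monte Carlo parameter
    sweeps over cost ratio, conformity, initial willingness and reproduction
    number, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
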