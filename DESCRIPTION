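Package: senespread
Title: Modelling the Spread of Cellular Senescence in a Cell Monolayer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-tier modelling framework for the spread of cellular
    senescence through paracrine (SASP) and juxtacrine signalling in a 2D
    cell monolayer. Provides an analytic minimal model of spread probability
    built on ligand-capture theory for cell-covered surfaces (capture
    lengths, autocrine probabilities, annulus spread rates, Poisson-binomial
    spread classification and phase-boundary scans), a particle-based
    Brownian simulation of ligand diffusion and capture that validates the
    analytic capture law, an event-driven stochastic simulator of senescence
    spread from a lesion with delayed maturation, juxtacrine fire-break
    rules and secondary-SASP scaling, and a likelihood-free (ABC-SMC)
    inference pipeline that recovers signalling parameters from a
    seeded-lesion experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    tools,
    pracma,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
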