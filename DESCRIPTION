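Package: ifnwave
Title: First- and Second-Responder Dynamics of the Type I Interferon Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation model of population-level type I
    interferon (IFN-I) response dynamics in TLR-stimulated immune cells, in
    which a small fixed fraction of first responders secretes IFN-alpha that
    recruits a larger pool of second responders through a Hill-gated paracrine
    threshold. Provides deterministic simulation and steady-state solutions;
    joint multi-condition nonlinear least-squares fitting with shared,
    condition-specific and fixed parameters, seeded log-space multistarts,
    one-sided handling of concentrations left-censored at the ELISA limit of
    quantification, and parsimony comparison of nested constraint structures;
    a synthetic-data generator emulating percent-positive flow-cytometry
    readouts (binomial cell counting) and ELISA concentrations (multiplicative
    lognormal noise with censoring); and pipeline helpers for dose-response
    scenarios, parameter-recovery studies, fold-change transformation and
    replicate-spread summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
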