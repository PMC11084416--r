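Package: aldress
Title: Drug Causality Assessment for DRESS Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for attributing drug causality in drug reaction with
    eosinophilia and systemic symptoms (DRESS). Implements a DRESS-specific
    causality score (ALDRESS) alongside the Spanish Pharmacovigilance System
    (SEFV) algorithm and the RegiSCAR diagnostic score as a declarative,
    config-driven rules engine; diagnostic-accuracy evaluation with exact
    Clopper-Pearson confidence intervals and Fisher's exact test; Cohen's
    kappa (unweighted and weighted) with asymptotic standard errors and
    Landis-Koch interpretation; and a seeded generator of synthetic
    case-control cohorts with planted ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    optparse,
    withr,
    stats,
    tools,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
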