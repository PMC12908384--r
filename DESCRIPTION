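Package: nkbind
Title: Eco-Evolutionary Double-Bind Dynamics of Radiation and NK-Cell Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying an evolutionary double bind between
    radiotherapy and natural-killer (NK) cell therapy in mixed cultures of
    radiation-sensitive and radiation-resistant tumour cells. Implements a
    three-population Lotka-Volterra competition model with logistic NK
    growth, a synthetic co-culture data generator emulating a
    multi-fraction seeding design, a staged bounded least-squares fitting
    pipeline with per-replicate estimates and mean/SEM summaries,
    double-bind diagnostics (differential NK kill rates, cost of
    resistance, competition-regime classification), and a reduced
    two-population model with an explicit double-bind parameter for
    treatment-sweep simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
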