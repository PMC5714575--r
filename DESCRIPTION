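Package: ntcprefit
Title: Algorithm-Specific NTCP Model Parameters from Dose-Volume Histograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normal tissue complication probability (NTCP) modelling of
    radiation-induced lung complications from dose-volume histograms (DVHs).
    Implements the Lyman-Kutcher-Burman (LKB) and relative seriality (RS)
    dose-response models with equivalent uniform dose (EUD) reduction and
    linear-quadratic (EQD2) fractionation correction, and refits
    algorithm-specific model parameters so that DVHs calculated with one dose
    calculation algorithm reproduce the NTCP values obtained with a reference
    algorithm, holding the tissue-architecture parameter fixed. Provides
    bootstrap and curvature-based standard errors for the refitted parameters,
    rectangular-grid NTCP confidence bands propagated from published 1D
    parameter confidence intervals, a registry of published lung NTCP
    parameter sets, and a seeded generator of synthetic paired-DVH cohorts
    for tangential breast, locoregional breast and lung treatments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
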