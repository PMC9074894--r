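Package: meetmiddle
Title: Meet-in-the-Middle Screening of DNA Methylation Mediators of
    Prenatal Exposure Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a five-step 'meet-in-the-middle' analysis for
    testing whether cord-blood DNA methylation CpG sites mediate
    associations between prenatal environmental exposures and children's
    cognitive, behavioral, and mental health outcomes. Keyword-driven
    pathway selection reduces the CpG universe per outcome; sequential
    FDR-corrected regression screens (outcome-CpG, exposure-CpG,
    exposure-outcome) identify candidate mediation triangles; and a
    bootstrap mediation analysis decomposes the exposure effect into
    direct and indirect components on the link scale. Includes methylation
    preprocessing (logit2 M-values, cell-composition residualization,
    coverage QC, outlier trimming, discovery/validation splitting), a
    standard EWAS comparison mode, and a synthetic-cohort generator with
    a ground-truth ledger of planted mediation triangles so the whole
    cascade is testable without access to cohort data.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
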