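Package: melscreen
Title: Prognostic Somatic Mutation Screening for Metastatic Melanoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens somatic mutations in metastatic melanoma cohorts for
    prognostic value. Implements a quality/impact/panel mutation filtering
    cascade with per-step accounting, ultraviolet-signature spectrum
    classification (C>T at dipyrimidine sites, tandem CC>TT), a
    deceased-versus-alive fold-change gene prioritization rule, gene-wise
    age-adjusted Cox proportional-hazards screening under Benjamini-Hochberg
    false discovery rate control across two overall-survival time origins,
    RNA-level confirmation of DNA mutations with a gene-level expressed-mutation
    rule, mutation/copy-number/expression integration, and Monte-Carlo power
    analysis for survival screens. Includes a synthetic cohort generator that
    reproduces the statistical structure the analysis assumes (overdispersed
    mutation burden, UV-dominated spectra, low per-gene prevalence, planted
    hazard ratios, censored exponential survival), so the full pipeline is
    testable without controlled-access data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
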