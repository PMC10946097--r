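Package: dtthiv
Title: Phenotyping Difficult-to-Treat HIV in Longitudinal Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Operational phenotyping of difficult-to-treat HIV from national
    HIV-registry extracts. Implements five longitudinal category rules
    (advanced resistance, four-drug regimen, salvage therapy, recent
    virologic failure, and repeated regimen switches after failure) over
    per-drug treatment episodes, viral-load series, and interpreted
    resistance results; derives treatment outcomes (viral suppression and
    dichotomized patient-reported health) with crude and covariate-adjusted
    odds ratios; and ships a seeded synthetic registry generator with
    planted ground-truth labels so the whole pipeline is testable without
    access to confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
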