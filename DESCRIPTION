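Package: omscreen
Title: Lexicon-Based Screening of Free-Text Primary Care Records for Otitis Media
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based screening of uncoded primary care consultation notes
    for visits where otitis media (OM) was a diagnosis under consideration.
    Implements an auditable exact-term lexicon matcher with an
    exclusion-word combination rule, a diagnostic-accuracy evaluation
    harness (sensitivity, specificity, predictive values and likelihood
    ratios with exact and log-method confidence intervals), a clinician
    chart-review workflow (independent labelling, consensus adjudication,
    discrepancy reports), and a seeded synthetic note generator so the whole
    pipeline is testable without real patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    stringi,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
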