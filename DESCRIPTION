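Package: smsense
Title: Digital Phenotyping of Adolescent Social Media Use from Smartphone Sensing Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for turning raw smartphone mobile-sensing event logs
    (AWARE-style 'applications foreground' launches plus auxiliary sensor
    rows) into analyzable social-media usage phenotypes. Reconstructs app
    usage episodes with explicit termination rules, computes valid-minute
    data-yield ratios and the 30-minute valid-hour zero-versus-missing
    rule, extracts hourly and daily duration and checking features per
    social-media category (research-coded narrow and broad, Play-Store
    defined, and survey-defined popular apps), and summarizes them with
    between/within-person variance decompositions (one-way random-effects
    ICC), repeated-measures correlations, and per-app descriptive tables.
    Includes a synthetic cohort generator with known ground truth for
    validating every pipeline stage, and a multi-coder Fleiss/Cohen kappa
    for app categorization agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
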