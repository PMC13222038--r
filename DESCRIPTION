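Package: temporg
Title: Temporal Organization Analysis of Free Recall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the temporal contiguity effect in free recall:
    percentile-rank temporal organization scores, lag-conditional response
    probabilities (lag-CRP), one-sample tests against chance-level clustering,
    group-by-timepoint recall-accuracy and score models with cluster-bootstrap
    standard errors, and a two-part zero-inflated beta regression for
    conditional response probabilities. Includes a synthetic-cohort generator
    emulating a two-group (non-injured comparison vs. traumatic brain injury),
    multi-timepoint narrative and wordlist recall design, so the full pipeline
    runs and can be validated without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    fitdistrplus,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
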