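Package: brainprofiles
Title: Latent Profiles of Brain Structure and Psychopathology Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies latent profiles of subcortical volume and orbitofrontal
    cortical thickness with a weighted Gaussian finite-mixture EM engine, and
    compares profiles on concurrent and follow-up psychopathology outcomes with
    a manual three-step (pseudo-class draw) procedure, cluster-robust Wald
    inference, classification-error (BCH) correction, and Benjamini-Hochberg
    false discovery rate control. Ships a seeded synthetic-cohort generator
    emulating a multisite, family-clustered, probability-weighted pediatric
    neuroimaging study so the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
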