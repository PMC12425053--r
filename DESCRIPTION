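Package: noveltydiary
Title: Event Novelty Metrics and Multilevel Analysis for Autobiographical Diary Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intensive-longitudinal (daily diary) studies of event
    novelty and autobiographical memory. Computes event-level relative semantic
    similarity from text embeddings, relative emotion similarity from rating
    vectors, and encoding-to-recall memory stability; scores recall narratives
    for episodic detail with a transparent Autobiographical-Interview-style
    rule backend; fits multilevel models with a singular-fit fallback, Tukey-
    adjusted marginal-mean contrasts and per-level simple slopes; and generates
    fully synthetic diary datasets with known ground truth for parameter-
    recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
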