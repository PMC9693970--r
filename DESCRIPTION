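Package: gaitmark
Title: Insole Gait Analysis for Parkinsonian Gait Markers
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-foot, eight-sensor force-sensitive
    insole recordings of the vertical ground reaction force (VGRF). Segments
    gait cycles via the differential GRF between the right and left foot,
    labels stance, swing and double-limb-support phases, extracts per-cycle
    kinematic parameters with per-subject central-tendency and dispersion
    indices, summarises whole-trial force dynamics, and compares
    Parkinson's-disease-like and healthy-like groups with pooled-variance
    t-tests (Bonferroni-corrected) and Mann-Whitney ROC analysis. Includes a
    synthetic insole-gait simulator with ground-truth gait events so the
    whole pipeline is testable without access to clinical datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
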