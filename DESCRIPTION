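Package: normdev
Title: Normative Modeling of Brain Morphometry and Extreme-Deviation Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level normative modeling of regional brain
    morphometry (cortical thickness, cortical surface area, subcortical
    volume). Fits per-region lifespan normative models by Bayesian linear
    regression with sinh-arcsinh likelihood warping, calibrates fitted
    models to unseen scanner sites using reference controls, and scores
    per-subject deviation Z-scores. Downstream tools map extreme
    deviations (|Z| > 2) per region and per individual across diagnostic
    groups, and run permutation-based group-difference and
    trait-association inference with nested multiplicity correction,
    propensity-score matching, and per-individual deviation-burden tests.
    Includes a synthetic multi-site cohort simulator with known ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
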