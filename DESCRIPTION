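Package: cpmr
Title: Connectome-Based Predictive Modeling of Behavioral Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates whole-brain connectome-based predictive
    models (CPM) of a behavioral severity score from resting-state functional
    connectivity. Covers framewise-displacement scrubbing and Fisher r-to-z
    network construction, leave-one-out consensus edge selection with partial
    Spearman correlation and nuisance covariates, a two-feature linear model
    over summed edge strengths, permutation inference, selection-threshold
    optimization, dependent-correlation model comparison (Steiger's Z),
    computational lesion analysis over functional networks, and a synthetic
    cohort generator with planted brain-behavior structure for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
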