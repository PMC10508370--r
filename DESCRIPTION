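Package: pwlmmtree
Title: Piecewise Linear Mixed-Model Trees for Longitudinal Subgroup Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits piecewise (two-segment) linear mixed-effects models to
    weekly repeated-measures outcomes and discovers moderator-defined
    subgroups with distinct trajectories via model-based recursive
    partitioning with globally estimated random effects.  Includes a
    synthetic longitudinal cohort generator with planted subgroup
    structure and study-style inclusion filters, score-based parameter
    instability tests (sup-LM and categorical), AIC-based breakpoint and
    tree-depth selection, user-level train/test splitting and k-fold
    cross-validation, and reporting utilities (log-scale
    back-transformation, percent change, caterpillar intervals,
    descriptive tables).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
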