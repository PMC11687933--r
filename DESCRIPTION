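Package: dsimmune
Title: Immune Dysregulation Analysis for Trisomy 21 Cohorts and JAK-Inhibition Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies immune dysregulation in Down syndrome (trisomy 21)
    cohort studies and longitudinal JAK-inhibitor trials. Implements
    bead-array autoantibody normalization (per-sample MAD transform),
    control-percentile positivity calling and Fisher-exact enrichment;
    composite interferon and cytokine scores against a euploid reference
    with covariate adjustment; beta regression on immune-cell cluster
    proportions; detection-limit imputation and mixed-model differential
    abundance for plasma analytes; and trial endpoint evaluation
    (baseline-change trajectories, upper-limit-of-normal autoantibody
    response, safety rules). A synthetic cohort generator with the same
    statistical structure makes every stage testable without access to
    participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    yaml,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
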