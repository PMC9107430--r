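Package: fcreact
Title: Functional Connectivity Reactivity to a Levodopa Challenge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pharmacological-challenge resting-state
    fMRI studies of Parkinson's disease tremor. Builds subject- and
    session-wise Fisher-z functional connectivity between dopaminergic
    (basal ganglia) and cholinergic (basal forebrain) seed regions and
    cortical parcels, computes edge-wise functional reactivity (connectivity
    change rates between OFF- and ON-medication sessions) and tremor
    responsiveness from UPDRS-III sub-scores, splits patients into
    dopamine-resistant and dopamine-responsive tremor groups at the cohort
    median, identifies discriminating edges by stability selection over
    resampled cross-validated L1-penalized logistic models, and runs the
    downstream covariate-adjusted group statistics (general linear models,
    paired tests, mixed-model group-by-status interaction, partial
    correlation, network-level summaries against controls). Includes a
    synthetic cohort generator with a planted differential edge so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lme4,
    lmerTest,
    nortest,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
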