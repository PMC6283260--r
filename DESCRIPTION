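Package: corexad
Title: Hierarchical Correlation Explanation for Multimodal Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers hierarchies of discrete latent factors that maximize the
    explained total correlation (multivariate mutual information) over
    multimodal biomarker panels, and carries the factors through a complete
    progression-modelling workflow: covariate residualization of brain
    measures, a longitudinal cognitive composite, diagnostic trajectory
    grouping, ensemble feature selection, gradient-boosted classification of
    progression contrasts with McNemar model comparison, and bootstrap
    stepwise regression stability selection for continuous outcomes. Includes
    a synthetic-cohort generator that emulates an aging-cohort study design
    (plasma analyte blocks, CSF hallmarks, APOE allele counts, bilateral
    brain regions, diagnosis trajectories) so the full pipeline is testable
    without access-controlled data.
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
    class,
    rpart,
    caret,
    glmnet,
    xgboost,
    mclust,
    igraph,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
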