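Package: ProteoBoneAge
Title: Longitudinal Serum Proteomics of Bone Mineral Density, Osteoporosis
    Risk and Proteomic Biological Age
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for proteome-wide studies of
    bone aging in longitudinal cohorts. Generates synthetic three-visit
    cohorts with known ground truth (serum protein abundances with
    left-censored missingness, bone mineral density at two skeletal sites,
    covariates, and a latent bone-aging process); preprocesses abundances
    (half-minimum imputation, z-standardization, T-score classification,
    fold-change screening with Benjamini-Hochberg control, PCA batch
    inspection); selects osteoporosis-related proteins by gradient boosting
    with SHAP attributions and by L1-penalized logistic regression; estimates
    protein-BMD associations per cohort with random-intercept linear mixed
    models pooled by DerSimonian-Laird random-effects meta-analysis; builds
    protein risk scores; classifies BMD trajectories with a latent-class
    growth mixture fitted by EM; fits Cox proportional-hazards and restricted
    cubic spline dose-response models for incident osteoporosis; derives a
    Klemera-Doubal proteomic biological age and its acceleration; and runs
    two-sample Mendelian randomization (Wald ratio, IVW, MR-Egger, weighted
    median, mode-based estimators) on GWAS summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    glmnet,
    xgboost,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Proteomics, Epidemiology, Survival, Regression, Software
RoxygenNote: 7.3.3
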