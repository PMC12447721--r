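Package: symptomics
Title: Explainable Multi-Output Neural Networks Linking 'Omics Profiles to
    Clinical Symptom Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a multi-task feed-forward neural network that maps a
    high-dimensional 'omics matrix (microbial species or KEGG gene
    abundances, immune cell frequencies, metabolite intensities, blood
    labs) onto a mixed-type panel of clinical symptom scores (binary,
    categorical and continuous on a 0-1 severity scale), then decodes the
    fitted model with Shapley-value feature attribution to separate
    disease-specific from symptom-specific biomarkers.  Includes the
    surrounding machinery needed to use and test such models end to end:
    preprocessing (standardization, abundance and prevalence filters,
    confounder residualization, score scaling), random under-sampling for
    class imbalance, stratified cross-validation, baseline classifiers,
    external-cohort feature alignment with zero imputation, module
    eigengene correlation networks with differential comparisons, and a
    seeded synthetic multi-omics cohort generator with a planted-effect
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    glmnet,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
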