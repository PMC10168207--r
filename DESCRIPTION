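Package: deepcombat
Title: CVAE-Plus-ComBat Harmonization of Multi-Batch Feature Matrices
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Harmonizes multi-batch, subject-by-feature matrices (e.g. regional
    cortical thickness from multi-scanner neuroimaging studies) while preserving
    biological covariate effects. Implements empirical-Bayes ComBat and CovBat,
    a fully-connected conditional variational autoencoder (CVAE) trained with a
    cyclic KL-annealing schedule, and the DeepComBat three-stage harmonization
    that combines latent-space ComBat, counterfactual decoding to a reference
    batch, and residual ComBat. Ships an evaluation battery (k-sample
    Anderson-Darling tests, feature-wise regression, MANOVA with Pillai's trace,
    kBET, batch-prediction AUROC), latent log-variance tuning diagnostics, a
    seeded synthetic multi-batch data generator with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    glmnet,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
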