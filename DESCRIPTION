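Package: srsprog
Title: Sensitivity of Brain-Metastasis Progression Definitions in Radiomic
    Outcome Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the definition of brain-metastasis
    progression after stereotactic radiosurgery changes the measured
    performance of a pre-treatment MRI radiomic classifier. Provides a
    per-lesion progression-labelling engine over a grid of follow-up windows,
    size-change metrics (orthogonal-diameter volume proxy and RANO-BM
    diameter) and treatment-related size-change adjudication schemes; an
    image preprocessing and 107-feature radiomic extraction stage (isotropic
    resampling, brain-masked z-score normalisation, fixed-bin-count texture
    matrices); a bootstrap out-of-bag evaluation harness with
    correlation-based feature filtering, Bayesian hyperparameter search,
    random-forest classification, training-set operating points and
    feature-importance stability aggregation; and a synthetic cohort
    generator (longitudinal lesion size trajectories with pseudo-progression
    and radiation-necrosis phenomena, plus feature tables with controlled
    signal) so the whole pipeline is testable without clinical data.
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
    jsonlite,
    lhs,
    purrr,
    ranger,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
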