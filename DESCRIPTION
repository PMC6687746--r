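Package: ccamodes
Title: Brain-Behaviour Modes of Covariation via PCA-CCA with Permutation
    Inference
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies modes of covariation between a subjects-by-connections
    functional connectivity matrix and a subjects-by-items behavioural table.
    Implements the full analysis pipeline: quality control (low-signal region
    exclusion, head-motion subject exclusion, near-constant item filtering,
    median imputation), confound regression (mean framewise displacement and
    one-hot scanner site) and standardization, PCA dimensionality reduction
    followed by canonical correlation analysis, maximum-statistic permutation
    inference with family-wise error control and Bonferroni-corrected selection
    of the PCA dimensionality, multiple hold-out validation, and loading-based
    interpretation of the resulting modes. Ships a two-view latent-factor
    simulator with planted modes, confound effects, missingness and
    near-constant items for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'ModelClasses.R'
    'utils.R'
    'dataio.R'
    'preprocess.R'
    'cca.R'
    'permutation.R'
    'holdout.R'
    'report.R'
    'synthetic.R'
    'pipeline.R'
    'ccamodes-package.R'
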