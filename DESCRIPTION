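Package: ccamodes
Title: Brain-Behaviour Mode Discovery by CCA-ICA with Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and validation of linked modes of covariation between
    a brain-imaging block and a behavioural block in the same participants.
    Implements the full analysis pipeline: cleaning, nearest-neighbour
    imputation, confound residualisation and rank-based inverse normal
    transformation; PCA reduction followed by canonical correlation analysis
    and a fastICA rotation of the canonical scores into interpretable modes;
    split-half reliability for dimensionality selection; max-statistic
    permutation tests with family-wise error control; out-of-sample
    projection of mode weights onto an independent cohort with
    spin-permutation spatial nulls and bootstrap confidence intervals; and
    post-hoc association models (diagnosis contrasts with Tukey adjustment,
    comorbidity trends, robustness re-runs). Includes a synthetic-data
    generator with planted cross-block latent modes so every stage is
    testable without access-controlled cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'associate.R'
    'ccamodes-package.R'
    'decompose.R'
    'inference.R'
    'io.R'
    'pipeline.R'
    'preprocess.R'
    'project.R'
    'reliability.R'
    'synthetic.R'
    'utils.R'
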