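Package: utrocular
Title: Simulation and Decoding of Eye-of-Origin Signals in Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying utrocular discrimination (judging which eye
    saw a monocular stimulus) with multivoxel pattern analysis. Provides a
    forward simulator of an ocular-dominance cortical sheet sampled into
    BOLD-like voxel time series under a block design, the template-correlation
    classifier with training-only T-statistic voxel selection and
    leave-one-run-out cross-validation, a univariate mean-signal decoder,
    permutation-based inference with Bonferroni correction, analytic t and
    correlation tests, and equal-variance signal-detection analysis
    (sensitivity d' and criterion) of behavioral eye-discrimination sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
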