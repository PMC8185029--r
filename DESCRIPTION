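Package: gammaSME
Title: Gamma-Band Subsequent Memory Effect Decoding from Intracranial
    Field Potentials
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and single-trial decoding of the subsequent memory
    effect (SME) in multichannel cortical field-potential recordings.
    Provides a synthetic 1/f electrocorticography generator with
    condition-dependent gamma-band power effects, common-average
    re-referencing and epoching, Morlet-wavelet time-frequency power with
    resting-baseline normalization, band/window feature aggregation,
    two-sample t-statistic SME maps with Bonferroni correction and
    top-fraction feature filtering, and remembered/forgotten classification
    with an RBF-kernel support vector machine under repeated stratified
    random splits, including label-permutation chance calibration and
    LDA/FLDA comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    data.table,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    MASS,
    nortest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
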