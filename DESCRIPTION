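Package: ecochg
Title: Objective Detection of Cochlear Microphonic Responses in
    Intracochlear Electrocochleography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for objective, examiner-independent detection of cochlear
    microphonic (CM/DIF) responses in intracochlear electrocochleography
    (ECochG) recordings. Implements the preprocessing chain used for
    epoch-ensemble recordings (stitching-artifact removal, Gaussian-weighted
    epoch screening with correlation-based exclusion, zero-phase Butterworth
    band-pass filtering, DIF/SUM derivation and plus-minus SNR estimation),
    three detectors (a one-sample Hotelling's T-squared test on time-voltage
    means with per-frequency tuning of the window count, a split-buffer
    correlation statistic with a logistic read-out, and a compact
    convolutional network classifier operating on Morlet wavelet scalograms),
    evaluation statistics (confusion metrics, ROC/AUC, paired one-sided
    DeLong comparison, Fleiss' kappa for multi-rater agreement), and a
    synthetic-recording generator with known ground truth for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io.R'
    'consensus.R'
    'synthetic.R'
    'filter.R'
    'preprocess.R'
    'tvm.R'
    'hotelling.R'
    'correlation.R'
    'scalogram.R'
    'cnn.R'
    'classifier.R'
    'evaluation.R'
    'benchmark.R'
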