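Package: mrmprep
Title: Quality Assessment and Normalization for Label-Free MRM Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pre-processing for label-free multiple reaction monitoring (MRM)
    transition reports: retention-time drift correction and adjusted-CV
    transition screening, per-peptide robust two-way modelling by iteratively
    reweighted least squares with Huber weights, transition- and run-level
    quality summaries (median weight, weight IQR, normalized unscaled standard
    error), five between-run normalization methods (global median, quantile,
    cyclic loess, control-subset median, rank-invariant set), and a
    group-aware MSE/CV evaluation framework with a Welch t-test screen.
    Includes a synthetic MRM data generator with ground truth and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, QualityControl, Normalization,
    Preprocessing
RoxygenNote: 7.3.3
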