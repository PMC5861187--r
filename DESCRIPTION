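Package: netpsych
Title: Psychometric-Linked Functional Brain Network Discovery and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, seed-reproducible pipeline for discovering
    functional brain networks linked to psychometric scores from resting-state
    connectivity, and for evaluating them with multiclass classifiers.
    Stages: voxelwise gray-matter regression with a total-brain-volume
    covariate and per-parcel permutation small-volume correction; peak-sphere
    region-of-interest definition with overlap deduplication; nuisance
    regression, bandpass filtering and per-subject ROI correlation matrices;
    edge-wise regression with network-based-statistic permutation
    familywise-error correction and edge-count targeting; and 8-class
    one-against-all RBF support-vector-machine classifiers with grid-searched
    hyperparameters, leave-one-out cross-validation, and exact binomial
    chance-level comparisons. A synthetic-data module generates score tables,
    gray-matter volumes and ROI time series with known planted effects so
    every stage can be validated against a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    signal,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
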