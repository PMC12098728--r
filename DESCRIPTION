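Package: sozpipe
Title: Interictal Intracranial EEG Features and Seizure Onset Zone Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and machine-learning pipeline for localizing
    the seizure onset zone (SOZ) and resection zone (RZ) from interictal
    intracranial EEG. Computes 45 per-channel features: spike and
    high-frequency-oscillation rates and amplitudes, Welch band power in nine
    frequency bands, and graph metrics (node strength, eigenvector
    centrality) of amplitude-envelope-correlation and phase-locking-value
    functional connectivity networks in eight bands. Provides node-level and
    patient-level cross-validated classifier evaluation with imbalance-aware
    support vector machines and tree ensembles, feature-subset comparison
    statistics, AUC-versus-feature-count power fits, an optimal-operating-point
    construction, and a permutation test for enrichment of classifier false
    positives inside the resection zone. Includes a synthetic multichannel
    iEEG cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    minpack.lm,
    ranger,
    signal,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
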