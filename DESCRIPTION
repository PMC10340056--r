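Package: HistoTuneR
Title: Metaheuristic-Tuned Lightweight Convolutional Networks for
    Histopathology Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale pipeline for five-class lung and colon
    histopathology image classification. Implements the Al-Biruni Earth
    Radius (BER) and Coati Optimization (COA) population metaheuristics as
    bound-constrained minimizers, a lightweight feature extractor built
    from depthwise-separable convolutions with channel shuffle and
    efficient channel attention (ECA), and a convolutional-recurrent
    classifier head trained with label-smoothing cross-entropy. A
    synthetic hematoxylin-and-eosin-like image generator with controllable
    class separability makes every stage testable without external data.
    BER tunes the extractor hyperparameters and COA the classifier head,
    both minimizing the validation error rate; evaluation reports
    per-class and macro accuracy, precision, recall, F-score and
    one-vs-rest AUC.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    caret,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'HistoTuneR-package.R'
    'ber.R'
    'coa.R'
    'synthetic.R'
    'evaluation.R'
    'nn-ops.R'
    'nn-engine.R'
    'extractor.R'
    'crnn.R'
    'searchspace.R'
    'tuning.R'
    'config.R'
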