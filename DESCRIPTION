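Package: slimscan
Title: Prediction of SH3-, WW- and PDZ-Binding Linear Peptide Motifs
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-based prediction of short linear peptide motifs
    (SLiMs) that bind the three most common peptide-recognition modules:
    SH3, WW and PDZ domains. Implements four independent prediction
    strategies over sliding sequence windows: a radial-basis-function
    support vector machine trained on amino-acid, dipeptide and
    over-represented-tripeptide composition features; a frequency-based
    position-specific scoring matrix; regular-expression motif scanning;
    and exact motif-instance matching. Includes the dataset-construction
    rules (redundancy collapse, cross-class union negatives, balanced
    subsampling), a stratified five-fold cross-validation harness with
    confusion-matrix metrics (sensitivity, specificity, accuracy, MCC)
    and ROC/AUC, a synthetic planted-motif peptide generator for
    benchmarking, and a command-line scanner producing a combined
    tabular report of all methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
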