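Package: hqdr
Title: Hybrid Quantum-Classical Neural Networks for Drug Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts anticancer drug response (IC50) for drug/cell-line pairs
    with a hybrid quantum-classical neural network. Drugs enter as SMILES
    strings converted to molecular graphs with 78-dimensional binary atom
    features and are encoded by a graph convolutional network; cell lines
    enter as 735-dimensional binary genomic-mutation vectors encoded by a
    1-D convolutional network. The two 128-dimensional embeddings are fused
    and fed to an 8-qubit quantum depth-infused layer: a data re-uploading
    variational circuit simulated by an exact dense statevector engine with
    adjoint-method gradients, implemented in C++. A classical twin model
    (two dense layers in place of the quantum head) supports controlled
    comparisons, including a training-set-size sweep. Ships a seeded
    synthetic data generator so the full pipeline runs without downloads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ChemmineR,
    ChemmineOB,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
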