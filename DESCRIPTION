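Package: pseucnn
Title: RNA Pseudouridine Site Prediction from Fourier Dinucleotide Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies RNA pseudouridine sites in center-aligned uridine
    windows. Each sequence is encoded with two dinucleotide physicochemical
    properties (free energy and hydrophilicity), converted to discrete
    Fourier transform amplitude spectra, and classified with a compact
    convolutional neural network whose dense head is sized by random-search
    hyperparameter optimization under stratified k-fold cross-validation.
    Includes a synthetic benchmark generator, FASTA/TSV input and output,
    and a command-line interface covering simulation, feature extraction,
    hyperparameter search, cross-validation, and prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
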