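Package: icering
Title: Ice-Ring Artefact Detection in Merged Macromolecular Diffraction Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects diffraction artefacts from hexagonal ice in integrated,
    scaled and merged macromolecular reflection data. Each candidate ice-ring
    resolution window is converted into a percentile-clipped 80x80
    two-dimensional histogram of observed intensities (or amplitudes) against
    resolution and classified by a small convolutional neural network with a
    sigmoid output; per-window verdicts are OR-aggregated into a dataset
    verdict. Includes a reader for MTZ reflection files and a plain-text
    reflection dialect, a blank-resolution-shell discriminator, SmoothGrad
    sensitivity maps, confusion-matrix evaluation metrics, and a
    Wilson-statistics reflection simulator that generates labelled synthetic
    corpora for training and testing the classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
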