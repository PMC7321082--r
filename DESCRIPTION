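Package: nearedge
Title: Predicting K-Edge X-ray Absorption Near-Edge Spectra from Local Atomic Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A structure-to-spectrum machine-learning pipeline for K-edge X-ray
    absorption near-edge structure (XANES) prediction. Featurises the local
    environment around an absorbing atom as a sorted Coulomb matrix or a
    charge-weighted radial distribution curve, trains a multilayer perceptron
    to map features onto discretised absorption cross-sections, post-processes
    predictions with an energy-dependent arctangent lifetime broadening, and
    evaluates models by repeated K-fold cross-validation, learning curves,
    peak-parity statistics, centile ranking, and encoded-radius histograms.
    Includes a seeded synthetic data generator (random Fe-centred clusters with
    a deterministic toy forward model) so the full pipeline is trainable and
    testable offline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
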