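Package: holocyte
Title: Holographic Flow Cytometry Simulation, Phase Reconstruction and
    Label-Free Cell Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for label-free classification of
    flowing cells from off-axis digital holograms. Provides a
    physics-based synthetic hologram generator for two overlapping cell
    populations, quantitative phase-map reconstruction (apodization,
    carrier demodulation, angular-spectrum refocusing with Tamura
    autofocus, reference-hologram aberration compensation, congruent
    least-squares phase unwrapping, denoising, segmentation and
    cropping), a 12-feature morpho-textural-phase descriptor, Kendall
    correlation and Relief feature selection with PCA and t-SNE
    embeddings, eight classical classifiers with stratified
    cross-validation and a feature-group ablation study, and a compact
    convolutional network built from inverted-residual bottleneck
    blocks trained directly on phase crops.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    rpart,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
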