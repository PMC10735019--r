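Package: trackqc
Title: Track Characterization and Image Quality Control for Neutron Autoradiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing etched nuclear tracks in neutron
    autoradiography micrographs and for automated quality control of the
    images prior to boron quantification in BNCT studies. Segments etched-pit
    objects by threshold binarization, 8-connected component labeling and
    watershed splitting; computes six per-track morphological and intensity
    descriptors (area, diameter, aspect ratio, roundness, heterogeneity,
    clumpiness) and 36 per-image summary features; reduces features by
    correlation-matrix PCA; and trains RBF support vector machine and dense
    neural network classifiers that accept or reject images at a
    precision-targeted decision threshold. Includes a physics-informed
    simulator of synthetic track images (boron neutron capture decay
    channels, energy-dependent pit size, light and focus corruption) with
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    e1071,
    jsonlite,
    png,
    tiff,
    yaml,
    tools,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
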