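Package: maci
Title: Multivariate Analysis of Congruent Ultrasound Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyses grayscale B-scan ultrasound image sequences of moving
    muscle tissue by multivariate analysis of congruent images (MACI): each
    frame is made congruent by a periodized 2-D discrete wavelet transform
    (Symlet 8 by default), the highest-variance coefficients form a frames x
    variables table, and a NIPALS principal component analysis of that table
    yields score trajectories, distance-to-model (DModX) diagnostics and
    loading images that localise the moving tissue. Movement structure
    (turning phases, adjacent-frame tissue-dynamics distances, repetition
    segmentation and similarity) is read off the score trajectory. A
    pyramidal Lucas-Kanade speckle-tracking module (segmented ROIs,
    whole-image grids, PCA of tracks, pennation angles) provides an
    independent reference analysis, and a speckle-sequence simulator with
    known displacement fields and phase labels provides ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'imageSequence.R'
    'wavelet-filters.R'
    'wavelet.R'
    'loadingImage.R'
    'maci-package.R'
    'pca.R'
    'trajectory.R'
    'tracking.R'
    'pipeline.R'
    'synthetic.R'
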