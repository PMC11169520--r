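Package: nucleoDHM
Title: Label-Free Nucleolus Quantification from Correlative DHM-Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies nucleoli in human cells from correlative digital
    holographic microscopy (DHM) and fluorescence image triplets. Segments
    nuclei from DAPI images by bimodal-histogram thresholding and nucleoli
    from GFP images by increasing-threshold local-maximum detection followed
    by two region-growing passes (one tuned for counting, one for area), with
    mitosis, clustered-cell and border filters. Extracts the clinical
    nucleolar parameters (nucleoli per cell, nucleolar area, nucleolar-to-
    nuclear area ratio), converts DHM phase shift to optical path length and
    computes the nucleolar optical-thickness index, and provides a compact
    U-net training harness with Dice loss, Adam optimisation and ensemble
    voting for segmenting phase images directly using fluorescence-derived
    labels. A synthetic correlative-triplet generator with analytic ground
    truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
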