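Package: bphpgeom
Title: Geometric and Spectral Analysis of Bacteriophytochrome Photosensory Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies conformational differences between bacteriophytochrome
    photosensory-module crystal structures: Smith-Waterman pairing of C-alpha
    traces, least-squares rigid superposition with iterative outlier rejection,
    residual PHY-domain rotation and translation after PAS-GAF core alignment,
    dimer interface offset angle between interface helix-bundle axes, PHY
    centroid distance and opening angle, crystallographic B-factor to
    r.m.s.-displacement conversion, and chromophore-pocket atom-pair distances.
    Also processes UV-vis absorption spectra (normalization,
    illuminated-minus-dark difference spectra, absorption-maximum extraction).
    A synthetic-data module generates two-subunit multi-domain C-alpha models
    with known interface geometry and two-band Pr/Pfr-like absorption spectra
    so that every pipeline stage is testable against constructed ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
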