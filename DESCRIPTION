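Package: silkcode
Title: Encoding, Synthesis, Decoding and Authentication of Edible
    Fluorescent Matrix Codes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An in-silico pipeline for edible fluorescent matrix-code
    taggants used in on-dose medicine authentication. Digital keys are
    encoded as n-by-n matrix codes read in three fluorescence channels
    (eCFP, eGFP, mKate2), rendered as synthetic fluorescence rasters with
    fabrication-like imperfections, and decoded either by a classical
    grid-thresholding reader or by a 2D convolutional neural network
    trained end-to-end inside the package. Decoded digitized keys are
    hashed (MD5/SHA-256/SHA-512) and authenticated against a JSON key
    registry. Includes a bit-error-ratio benchmark harness and
    photobleaching-style intensity-degradation sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    openssl,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
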