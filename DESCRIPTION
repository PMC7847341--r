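Package: geohnn
Title: Geometrically Regularized Hopfield Networks for Gray-Scale Image Enhancement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for enhancing 8-bit gray-scale images with a geometrically
    regularized modified Hopfield network. The package provides the classical
    binary/continuous Hopfield baseline with Hebbian storage and asynchronous
    Lyapunov descent, minimum-probability-flow (MPF) parameter estimation for
    bipolar networks, structure-tensor orientation fields with directional
    gradient energy and a spatially varying coupling field, a Q-class pixel
    labeling network with checkerboard sign-sequenced updates, bipolar
    bit-plane and ON/OFF ternary codecs, a five-metric perceptual evaluation
    suite (entropy, VIF, WPSNR, GLCM contrast and homogeneity), deterministic
    synthetic phantom fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
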