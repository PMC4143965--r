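Package: rsa3d
Title: Replicated 3D Point-Pattern Analysis of Cortical Synapses with
    Random Sequential Adsorption Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing the three-dimensional spatial distribution
    of synaptic junctions reconstructed from volume electron microscopy.
    Provides 3D point patterns in box windows with per-point Feret
    diameters, the translation edge-corrected Ripley K function and
    Besag L transform, random sequential adsorption (RSA) hard-sphere
    simulation with lognormal sizes, global Monte-Carlo envelope
    goodness-of-fit tests with leave-one-out parameterisation, aggregation
    of K functions across replicated patterns, a bootstrap test for
    differences between groups of replicates, random-thinning
    cross-validation of a common dense RSA model, and fixed-window density
    subsampling with rank-based layer comparisons. A reference table of
    per-sample synapse counts and volumes for rat somatosensory cortex and
    a synthetic-study generator are included so every stage can be run
    without raw image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    car,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
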