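Package: boldpatch
Title: Generative Adversarial Inpainting of Cortical Surface BOLD Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs lost or compromised resting-state BOLD signal on the
    cortical surface. Flattened per-frame BOLD maps are modelled with a deep
    convolutional generative adversarial network (DCGAN); compromised regions
    are inpainted frame by frame through masked latent-space optimization, and
    a boundary-diffusion baseline is provided for comparison. Includes an
    icosphere surface substrate with deterministic vertex-to-pixel flattening,
    a synthetic-cohort generator with individual-specific network-structured
    functional connectivity, the preprocessing arithmetic (session
    normalization, global signal regression, temporal smoothing, temporal
    signal-to-noise ratio), and an evaluation suite (per-vertex time-series
    recovery, seed-based Fisher-z functional-connectivity map similarity,
    most-similar-individual fingerprinting, amplitude recovery, mask-size
    sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
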