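Package: tunnelcall
Title: Base Calling, Assembly and Quantitation for Single-Molecule
    Tunneling-Current Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Computational pipeline for single-molecule quantum sequencing
    of short DNA by tunneling-current measurements in a nanogap electrode.
    Provides a synthetic trace simulator with ground-truth annotations,
    hysteresis-threshold signal detection with robust noise estimation,
    probabilistic base calling from Gaussian conductance histograms,
    transition-point (reading-direction) analysis and reference-free
    unfolding of duplicated readouts, greedy overlap-consensus assembly of
    short fragments with coverage and normalized-conductance heat maps, and
    single-base-marker counting for abundance-ratio estimation in
    two-variant mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
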