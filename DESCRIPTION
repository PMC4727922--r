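Package: cernacap
Title: Information Capacity of miRNA-Mediated ceRNA Regulatory Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic kinetic model of competing endogenous RNA (ceRNA)
    cross-talk: two ceRNA species repressed by a shared miRNA, each
    transcriptionally activated by its own transcription factor. Provides the
    deterministic steady state of the titration network, exact Gillespie
    simulation of its chemical master equation, the linear noise approximation
    (Jacobian, diffusion matrix and stationary covariance), and the
    small-noise Gaussian channel-capacity machinery used to compare
    post-transcriptional (miRNA-mediated) against direct transcriptional
    control of the target: response curves, amplitude of variation, optimal
    input distributions, channel capacities in bits and plug-in mutual
    information, together with configuration-driven parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
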