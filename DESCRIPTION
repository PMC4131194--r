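Package: gcio
Title: Input-Output Gain Analysis of Adult-Born Dentate Granule Cells
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extraction of intrinsic biophysical parameters and sinusoidal
    input-output gain statistics (average slope, slope variance, normalized
    offset) from current-clamp sweep bundles of dentate granule cells, with
    two-population inference (one- vs two-component Gaussian comparison,
    K-means, Ward hierarchical clustering, age-binned group probabilities,
    mean-variance parabolic fits, per-group correlations) and a ground-truthed
    synthetic cohort generator (curve-level archetypes and an exponential
    integrate-and-fire trace simulator) for end-to-end pipeline testing.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
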