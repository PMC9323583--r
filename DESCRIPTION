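Package: fdretina
Title: Box-Counting Fractal Dimension of Retinal OCT-Angiography
    Vasculature with Repeatability and Reproducibility Statistics
Version: 0.1.0
Authors@R:
    person("fdretina", "maintainers", email = "fdretina@example.org",
           role = c("aut", "cre"))
Description: Quantifies the complexity of the retinal vascular network on
    en-face OCT-angiography images via the binary box-counting fractal
    dimension (fixed-threshold binarisation, morphological skeletonisation
    with a continuity check, dyadic mesh box counts, log-log slope fit),
    and assesses measurement agreement across repeated scans and observers
    with Shrout-Fleiss intraclass correlation coefficients (exact F-based
    95% confidence intervals), coefficients of variation, Bland-Altman
    limits of agreement, paired t-tests and Cicchetti reliability labels.
    Includes a seeded synthetic-data generator (analytic fractal fixtures,
    stochastic vessel trees, repeat-scan perturbations, variance-components
    measurement tables) so the whole pipeline is testable without imaging
    hardware, plus a command-line entry point for end-to-end study runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
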