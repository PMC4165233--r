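Package: dendrofire
Title: Dendritic Morphology and Firing-Pattern Analysis for Pyramidal Cell Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how basal dendritic morphology shapes the
    somatic firing pattern of layer V prefrontal-cortex pyramidal cell models.
    Reads, validates, writes and recombines SWC neuronal reconstructions;
    computes per-tree morphometrics (median diameter, total length, volume,
    branch number, and mean electrotonic path length); assembles
    conductance-based compartmental cell models with uniform or
    distance-dependent basal channel distributions; integrates the branched
    cable equation with Hodgkin-Huxley style channels; applies
    input-resistance-normalized current-step protocols with interspike-interval
    based classification of responses as regular spiking, intrinsic bursting
    or quiescent; and runs the population pipeline (basal-by-apical simulation
    grids, majority-vote basal profiling, Mann-Whitney feature comparison,
    balanced Gaussian Bayes classification, feature correlation). A synthetic
    dendritic tree generator provides controllable two-class populations so
    the whole pipeline is testable without external reconstructions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
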