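Package: slfv
Title: Spatial Lambda-Fleming-Viot Coalescent Simulation and Neighborhood-Size Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Backward-in-time simulation of the spatial Lambda-Fleming-Viot
    (SLFV) coalescent on one- and two-dimensional toroidal landscapes:
    localized reproduction events select nearby lineages probabilistically
    and merge them into a relocated ancestor, producing spatially embedded,
    possibly multifurcating genealogies. Includes neutral mutation overlays
    (infinite sites and Kimura two-parameter sequences), spatial-genetic
    summary statistics (pairwise diversity, Watterson's estimator,
    isolation-by-distance regression, distance-class variograms), and
    rejection approximate Bayesian computation for joint estimation of
    neighborhood size and dispersal radius from georeferenced samples, with
    leave-one-out cross-validation of the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
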