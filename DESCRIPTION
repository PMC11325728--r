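Package: tls4d
Title: Spatiotemporal Registration and Growth Modeling for Time-Series
    Terrestrial Laser Scanning of Breeding Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for four-dimensional (space + time) analysis of terrestrial
    laser scanning (TLS) point clouds of row-crop breeding fields. Implements a
    two-phase spatiotemporal registration of per-session point clouds (terrain
    model based iterative closest point rough alignment followed by a
    bird's-eye-view Procrustes refinement on detected plot centroids), digital
    terrain model reconstruction and height normalization, Hausdorff-distance
    registration diagnostics, plot-level canopy trait extraction (height, area,
    volume, light interception), and hierarchical sigmoid growth-curve modeling
    (logistic, Gompertz, Richards) with genotype contrasts. A synthetic-field
    simulator generates ground-truthed multi-session clouds so the whole
    pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
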