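Package: angiometry
Title: Morphometrics of Engineered Microvascular Networks from Confocal Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification toolkit for engineered microvascular network
    cultures imaged as confocal z-stacks. Provides per-slice
    blur/filter/binarize preprocessing, 3D topology-preserving
    skeletonization, skeleton-graph extraction with branch-point and
    endpoint detection, and vessel-network morphometrics (total network
    length per mm3, vessel, branch and endpoint counts, average branch
    length); binary-mask colocalization; spheroid outgrowth area and
    fold-change quantification; dot-blot array densitometry with
    reference-spot normalization; protein-interaction graph summaries;
    and an assumption-gated statistical battery routing between
    ANOVA/Tukey, Welch ANOVA/Games-Howell, Kruskal-Wallis/Dunn and the
    trimmed-means Welch heteroscedastic F test. Includes synthetic
    phantom generators with exact ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    igraph,
    car,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
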