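Package: floramod
Title: Modularity and Shape Evolution of 3D Floral Landmark Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for landmark-based geometric morphometrics of flowers and
    phylogenetic comparative analysis of floral shape. Provides generalized
    Procrustes alignment, species mean shapes and PCA shape space; estimation
    of missing landmarks by thin-plate spline warping, mean substitution or
    regression, with remove-and-re-estimate validation and observer-error
    reports; covariance-ratio (CR) modularity tests with landmark-permutation
    nulls, effect sizes and two-sample strength-of-modularity comparisons,
    including a phylogenetically corrected variant; congruence-coefficient
    correlation matrices with maximum-likelihood comparison of modularity
    models by AICc; multivariate phylogenetic signal (Kmult), per-module
    Brownian rates with a rate-ratio test, discrete ancestral states,
    continuous trait-model fits (BM, lambda, early burst,
    Ornstein-Uhlenbeck) and greedy regime-shift detection; plus rarefaction
    and down-sampling robustness harnesses and a synthetic-data generator
    with known modular ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
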