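Package: sproutmorph
Title: Skeleton Morphometry of Angiogenic Sprouts and Spatial Profiling of
    Autophagy Puncta
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies three-dimensional angiogenic sprouting assays from
    z-projected confocal images. Builds calibrated maximum-intensity
    projections, segments sprouts with a set-level threshold, skeletonizes
    the mask and extracts the standard sprout morphometry panel (area, total
    skeleton length, tip-side endpoint count, average length and width
    coefficients, branch-point count). Profiles LC3B autophagosome puncta by
    distance from sprout endpoints in fixed micrometre or relative-percent
    contour bins, counts puncta-positive sprouts, and computes the
    mCherry/GFP tandem-reporter autophagic-flux ratio by sprout region.
    Includes a seeded synthetic sprout-image generator with exact ground
    truth, and group-comparison statistics (one-way ANOVA with Tukey
    post-hoc, unpaired t-tests) with tidy output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    tiff,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
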