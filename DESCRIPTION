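Package: bloomscale
Title: Scaling Flower Counts from Branches to Trees with Quantitative Structure Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the floral resources of individual trees by combining
    branch-level flower counts with cylinder-based 3D tree models (quantitative
    structure models, QSMs). Implements a two-part hurdle model of flower
    occurrence (binomial) and abundance (zero-truncated negative binomial) with
    nested random intercepts, farthest-distance subsampling of branch
    hierarchies, extraction and crown-position classification of flower-bearing
    branch units from cylinder tables, stochastic upscaling to whole-tree flower
    totals, tree-level negative-binomial allometries on stem diameter and crown
    volume, and pollen/nectar/bee-larvae resource budgets with combined
    bootstrap and Monte Carlo confidence intervals. Ships a synthetic-data
    generator producing branch datasets and replicated cylinder models with
    known ground truth so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    glmmTMB,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
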