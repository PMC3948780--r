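Package: patchpcf
Title: Patch-Edge Pair Correlation Analysis of Patchy Dryland Vegetation
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Spatial point-pattern inference for landscapes of non-overlapping,
    disc-shaped vegetation patches (e.g. nebkha-forming desert shrubs mapped as
    equivalent-area circles). Implements pair correlation and cross-correlation
    functions on shortest patch-edge distances, two constrained Monte Carlo
    null models (a homogeneous hard-core randomization conditioned on older
    cohorts, and a heterogeneous Poisson randomization that preserves observed
    patch density via a Gaussian kernel intensity), simulation envelopes with
    rank-based goodness-of-fit tests on an independent simulation set,
    grid-plot density/cover correlation tests, a decision framework mapping
    the statistical outcomes to recruitment-limitation hypotheses, and a
    synthetic multi-cohort landscape generator with known ground truth.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
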