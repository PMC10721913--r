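Package: eegmvpa
Title: Time-Resolved Multivariate Decoding of Epoched EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for time-resolved multivariate pattern
    analysis of epoched multichannel EEG. Implements deterministic signal
    conditioning (spectral resampling, zero-phase band-pass filtering,
    mastoid re-referencing, epoch cropping, baseline correction), automatic
    peak-to-peak artifact rejection with a data-driven threshold and
    interpolation-or-exclusion repair, per-timepoint linear discriminant
    decoding with shrinkage-regularised covariance and balanced k-fold
    cross-validation, cross-classification and temporal generalization,
    and group-level inference via threshold-free cluster enhancement with
    maximal-statistic permutation testing. A synthetic-EEG generator with
    known spatiotemporal category structure provides ground truth for every
    stage. Result objects are tibble-backed with broom-style tidy() and
    glance() methods and ggplot2 autoplot() methods.
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
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
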