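Package: destainr
Title: Post-Hoc Correlation of FM1-43 Destaining Kinetics with
    Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies vesicular release at individual presynaptic boutons
    from FM1-43 destaining time-lapse recordings and correlates it with
    post-hoc immunofluorescence of active-zone proteins measured on the
    same field. Provides puncta segmentation from the destaining
    difference image with kinetic quality control, rolling-ball background
    subtraction, translation-only multichannel registration, ROI-matched
    integrated-density quantification with mean normalization and
    high/low immunoreactivity grouping, and group-segregated unloading
    statistics (one-way ANOVA with Bonferroni-adjusted pairwise tests).
    A synthetic-experiment generator with exported ground truth makes
    every stage testable without microscope data.
License: MIT
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
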