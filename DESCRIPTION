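Package: wormwell
Title: Multiwell-Plate Worm Tracking, Photoresponse and Behavioural
    Fingerprint Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for high-resolution brightfield imaging of
    Caenorhabditis elegans in square-well multiwell plates viewed by a
    camera array. Detects the lattice of wells in a field of view by
    fitting a tiled well template with differential evolution, segments
    and tracks putative worm objects in masked video, filters non-worm
    objects with a small VGG-style convolutional network, computes
    time-resolved motion-mode statistics under blue-light
    photostimulation (bootstrap confidence bands, per-pulse response
    deltas, baseline shifts), summarises per-well behavioural features
    and runs the downstream statistics (quality control, imputation,
    z-normalisation, PCA, Kruskal-Wallis with Benjamini-Yekutieli
    control, hierarchical fingerprint clustering, a linear-mixed-model
    compound screen, and a random-forest strain classification
    protocol with recursive feature elimination), and merges
    experiment-record CSV files into per-video, per-well metadata. A
    synthetic-data module generates plate videos, labelled ROI images,
    strain-structured feature tables and metadata fixtures with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    png,
    Rcpp,
    EBImage,
    ranger,
    lmerTest,
    stats
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
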