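Package: synquant
Title: Hierarchical Bootstrap and Synapse Quantification for Nested
    Electrophysiology and Superresolution Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify synaptic function and structure from nested
    experimental designs. Implements per-cell electrophysiology metrics
    (evoked postsynaptic current amplitude, 20-80% rise time, paired-pulse
    ratio, stimulus-train amplitudes, hypertonic-sucrose charge as a
    readily-releasable-pool estimate, and template-based miniature-event
    detection), a three-level hierarchical bootstrap of a control-normalized
    ratio-of-ratios statistic with percentile confidence intervals and a
    directional null probability, control normalization with a
    normality-driven test-selection policy, side-view synapse line-profile
    quantification for STED/confocal images, and automatic two-dimensional
    puncta segmentation with overlap-based colocalization filtering. A
    synthetic-data module generates nested datasets, current traces and
    multi-channel synapse images with known ground truth so that every
    analysis stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    jsonlite,
    utils,
    withr,
    EBImage,
    tiff,
    pracma
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
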