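Package: embryoxai
Title: Accuracy, Agreement and Explanation-Overlap Evaluation for Embryo Stage Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation toolkit for ordinal embryo developmental-stage
    classification by human raters and deep-learning models. Implements the
    three-axis battery used in time-lapse embryology studies: classification
    accuracy and confusion analysis on the merged 7-stage ordinal coding
    (2-cell through blastocyst), chance-corrected agreement (quadratic-weighted
    Cohen's kappa with asymptotic confidence intervals, Fleiss' multirater
    kappa, Cochran's Q with Holm-adjusted McNemar post-hocs, chi-squared
    proportion tests, Wilcoxon matched-pairs signed-rank), and spatial-overlap
    analysis of explainable-AI outputs (Grad-CAM heatmap and LIME boundary
    overlays segmented into binary masks, compared by intersection-over-union).
    Includes a synthetic-data module that simulates rater tables with
    adjacent-stage error structure and renders Grad-CAM/LIME-style overlay
    images from known ground-truth attention regions, so the full pipeline is
    testable without clinical data or a trained network.
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
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
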