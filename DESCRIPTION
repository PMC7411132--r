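Package: phenocount
Title: Counting Reproductive Structures on Digitized Herbarium Specimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase pipeline for locating and counting reproductive
    structures (buds, flowers, fruits) on digitized herbarium sheets.
    Point annotations placed at the center of each visible structure are
    converted into calibrated dodecagon instance masks suitable for
    training instance-segmentation detectors; per-specimen counts are
    obtained by summing detections; and counts are evaluated with a
    counting-error framework (signed error, mean absolute error, R-squared,
    letter-value summaries, presence and dominance accuracy). Includes a
    synthetic herbarium-sheet generator with full ground truth, a
    deterministic color-threshold baseline detector, crowd-sourced
    annotation aggregation, and a scenario harness for per-species, global,
    and cross-species transfer experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    jsonlite,
    png,
    withr,
    ggplot2,
    generics,
    pracma,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
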