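Package: catrans
Title: Calcium Transient Detection and Group Statistics for Two-Photon Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for somatic two-photon calcium
    imaging of cortical neurons: rigid in-plane motion correction by phase
    cross-correlation, disk-ROI fluorescence pooling, median-baseline dF/F
    conversion, threshold-crossing calcium-event detection with flat-baseline
    validation, per-cell event counts in 5-minute windows, and the group
    statistics layer used to compare excitatory and inhibitory populations
    (normality-gated two-group tests with effect sizes, Kruskal-Wallis,
    mixed two-way ANOVA with partial eta squared, percent-change summaries,
    and cumulative-dose arithmetic for PTZ seizure-threshold titration).
    Includes a synthetic GCaMP6f-like trace and movie generator with full
    ground truth so every stage of the pipeline can be benchmarked without
    access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
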