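Package: CaMicroDomains
Title: Activity-Based Detection and Analysis of Calcium Microdomains in
    Two-Photon Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects astrocyte and neuronal calcium microdomains in
    two-photon fluorescence movies with an activity-based algorithm
    (sliding-boxcar thresholding, rise-time gating, spatiotemporal
    grouping, ANOVA false-positive control), extracts per-ROI dF/F
    traces and event metrics (amplitude, AUC, onset latency, adaptation
    slope), derives population metrics (fast/delayed onset classes,
    responsiveness tiers, pairwise synchrony, repeated-response score,
    barrel-area normalisation), scores whisker-discrimination behaviour
    from pose-estimation keypoint tables, and ships a ground-truthed
    synthetic-movie generator so the whole pipeline is verifiable
    without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'movie-io.R'
    'synthetic-movie.R'
    'amplitude-model.R'
    'synthetic-behavior.R'
    'detection.R'
    'event-analysis.R'
    'population-metrics.R'
    'behavior.R'
    'pipeline.R'
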