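Package: wormspan
Title: Survival Resilience and Healthspan Metrics for C. elegans Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies organismal stress resilience and healthspan in
    Caenorhabditis elegans assays. Implements the stress-span over
    life-span (S/L) resilience statistic computed from areas under
    Kaplan-Meier survival curves, relative survival gain (delta AUC
    percent), log-rank group comparisons, and dose-resilience profiling
    of literature records. Converts worm centroid trajectories into
    locomotion readouts (instantaneous speeds, directional shifts,
    paralysis calls, direction rescue index) and integrates five
    normalized fitness metrics into a single total-fitness score.
    Filters differential-expression tables by fold-change and FDR
    thresholds and scans 1.5-kb upstream promoter regions for degenerate
    SKN-1 binding consensus motifs. Ships synthetic-data generators
    (survival cohorts, correlated-random-walk tracks, promoters with
    planted motif sites, DE tables) so every pipeline stage is testable
    without external assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
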