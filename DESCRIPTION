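Package: mslchip
Title: ChIP-Seq Enrichment Tracks, Bound-Region Calling and Repeat
    Analysis for Drosophila Dosage Compensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds log2 ChIP/input enrichment-ratio tracks at fixed 10 bp
    resolution, applies windowed median smoothing with minimum-data-point
    discarding, and calls MSL-bound regions by a top-percentile threshold
    with gap merging and length/unit filters.  Quantifies the association
    of called regions with high-affinity sites (HAS) by nearest-distance
    binning against a seeded random control, profiles repeat-masked
    sequence content around transcription start sites for bound and
    unbound gene groups, and computes per-repeat-class RPKM enrichment
    ratios with bootstrap confidence intervals.  A synthetic-data
    generator emits genomes, tracks, annotations and count tables with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    withr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
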