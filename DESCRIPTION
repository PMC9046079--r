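Package: organoidScreen
Title: SSMD Decision Statistics and Spatial Normalization for Multiplexed
    Organoid High-Throughput Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed phenotypic organoid screens
    read out by paired lysozyme secretion assays (basal and stimulated) and
    ATP viability on 384-well plates. Implements log10 transformation with
    two-dimensional LOESS plate-surface correction, plate-median and
    control-median fold changes, robust replicate SSMD effect sizes (UMVUE),
    fold-change z-scores, decision-theoretic optimal SSMD critical values
    from noncentral-t false-positive/false-negative level curves, dual-assay
    hit calling with optimal-dose selection and per-target deduplication,
    screen-level quality control, and downstream compositional statistics
    (abundance-gated Fisher odds-ratio enrichment with FDR adjustment,
    Cohen's d effect sizes, min-max score scaling, and percentile exceedance
    fractions). Includes a synthetic-screen generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Normalization, QualityControl,
    StatisticalMethod
RoxygenNote: 7.3.3
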