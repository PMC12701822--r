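Package: dsbchrom
Title: Break-Centered Chromatin Analysis of Cas9-Induced Double-Strand Breaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies chromatin reorganization around programmed DNA
    double-strand breaks. Provides differential Hi-C aggregation and
    virtual-4C profiles around cut sites, sliding-square insulation scores
    with per-site damage-induced insulation change, stranded ChIP-seq
    meta-profiles with two-component (narrow peak + broad domain) width
    estimation and resection-driven strand asymmetry, and TAD-boundary
    truncation and distance-band statistics for the broad recombinase
    domain. Includes a synthetic-data generator that emulates the
    statistical structure of break-anchored contact maps and repair-factor
    coverage tracks, and a config-driven pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    minpack.lm,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
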