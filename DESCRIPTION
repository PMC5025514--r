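Package: polyArray
Title: Single-Locus SNP Array Design and Genotype-Cluster Analysis for
    Allopolyploid Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing Infinium-style SNP genotyping arrays in
    allopolyploid species and analysing the resulting data. Aggregates
    per-genotype variant calls into a cross-panel SNP summary matrix,
    applies the five-step single-locus filter cascade with an attrition
    report, extracts 50-bp assay probes and counts their genome-wide
    matches under a 35-consecutive-bp rule, fits and classifies two-colour
    intensity cluster patterns in theta space (including rescue of
    homoeolog-compressed shifted clusters and derivation of diploid
    cluster files), and reconciles genetic (Kosambi cM) and physical (bp)
    marker positions with concordance classification and rearranged-segment
    detection. A synthetic-data module simulates homoeologous subgenomes,
    variant panels, intensity clouds and doubled-haploid populations with
    known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
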