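Package: bulkQTL
Title: Bulk-Segregant QTL Mapping and Selective-Sweep Scanning for Pooled Sequencing
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci from pooled sequencing of
    phenotypic-extreme bulks (bulk segregant analysis). Computes per-SNP
    SNP-index, delta(SNP-index) with Monte-Carlo simulated confidence
    intervals, and the G statistic with tricube-kernel smoothing and
    log-normal null p-values; calls contiguous significant QTL regions.
    Includes windowed selective-sweep scans (nucleotide diversity, Hudson
    F_ST, reduction of diversity) between population panels with empirical
    quantile thresholds and segment merging, rule-based candidate-gene
    screening against gene models and tissue expression profiles, and a
    forward simulator of backcross (BC1) bulk-segregant experiments and
    three-population haplotype panels with engineered sweeps for testing
    the whole pipeline at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
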