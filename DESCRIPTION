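Package: chipcons
Title: Replicate-Consensus ChIP-Seq Peaks and Promoter Target-Gene Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of transcription-factor ChIP-Seq peak calls:
    builds high-confidence consensus peaks from per-replicate MACS2 narrowPeak
    files using a coordinate tolerance rule (peaks at the same locus within a
    few base pairs, supported by two or more replicates), annotates consensus
    peaks to genomic features and target genes via strand-aware promoter
    windows around the transcription start site, compares target-gene sets
    across conditions and genome assemblies, and tests gene-set overlaps with
    the hypergeometric distribution and mapping statistics with two-sample
    t-tests. A seedable synthetic-data generator produces gene models,
    replicate peak sets with planted promoter targets, and mapping-summary
    tables for benchmarking the pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    yaml,
    rlang,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
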