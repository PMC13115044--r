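Package: coldscreen
Title: Pooled Barcoded Mutant Screen Analysis for Cold Acclimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled insertional-mutagenesis screens that
    track barcoded mutant abundance across a control arm and a cold-stress arm,
    as used to find cold-acclimation genes in Chlamydomonas reinhardtii.
    Provides anchored barcode extraction from FASTQ and barcode-by-sample count
    matrices; seed-and-extend mapping of barcode-associated genomic flanking
    reads to insertion loci; rule-based annotation of insertions against gene
    models (promoter, UTR, exon, intron, intergenic); the relative-abundance
    ratio-of-ratios screening statistic with threshold-based hit calling,
    two-group mutant classification and gene-level aggregation; and a synthetic
    screen generator (genome, gene models, mutant library, fitness-driven
    abundance evolution, reads) with a per-mutant truth table so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
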