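Package: methtx
Title: Methylome and Transcriptome Integrity Analysis for
    Methylation-Deficient Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse the consequences of global DNA methylation
    loss on transcriptome integrity. Implements bisulfite methylation-call
    aggregation (replicate pooling, feature and window means, window
    methylation classes, de novo methylated window selection, gene-body and
    site-centred metaplots, germline-DMR scoring and a Fisher-exact DMR
    caller), sliding-window promoter CpG-class assignment (LCP/ICP/HCP) and
    promoter-methylation gene grouping, a negative-binomial Wald test for
    differential expression of genes, exons, transposable-element families
    and copies with threshold-based calling policies, fractional
    multi-mapping TE family quantification, upregulated-copy and
    ERV-proximal gene summaries, strand-resolved LTR metaplots, and a
    seven-criterion caller for cryptic intragenic transcription initiation.
    A seeded synthetic-data generator produces a toy genome, annotations,
    per-genotype methylomes and count matrices with planted effects so the
    whole pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    Biostrings,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
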