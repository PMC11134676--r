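Package: allelomethyl
Title: Haplotype-Resolved Integration of DNA Methylation and Allelic Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the two haplotypes of a hybrid (allodiploid)
    plant genome at the methylome and transcriptome level. Classifies cytosine
    sequence contexts (CpG, CHG, CHH) from genome sequence, computes weighted
    methylation levels over gene bodies and flanking regions and binned
    TSS-to-TTS metaprofiles, calls differentially methylated regions with a
    sliding-window two-proportion test under Benjamini-Hochberg control,
    chains homology anchors into collinear blocks to infer allelic gene
    pairs, applies replicate-consistency TPM filters and two-fold allelic
    differential-expression rules, and joins allelic expression classes with
    promoter/gene-body methylation to quantify the methylation-expression
    relationship. Includes a self-contained two-haplotype simulator with
    planted differentially methylated regions, planted allelic expression
    divergence and a configurable methylation-expression coupling, plus a
    machine-readable truth table for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
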