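Package: srnascape
Title: Discovery and Regulatory Analysis of Antisense and Intergenic Small RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A strand-aware pipeline for characterising the small noncoding
    RNA landscape of compact prokaryotic (especially archaeal) genomes from
    reference-guided transcript assemblies. Assembled transcripts are
    classified as antisense or intergenic sRNAs against a gene annotation
    with optional UTRs, quantified as transcripts per million (TPM) and
    filtered by replicate presence and expression thresholds. Antisense
    sRNAs are paired with their cis mRNA targets by genomic overlap and
    binned by binding region (5' UTR, CDS, 3' UTR); paired t tests compare
    sRNA and target expression, a negative-binomial Wald test calls
    condition-dependent differential expression with Benjamini-Hochberg FDR
    control, cross-tabulation flags anti-correlated cis pairs, and
    hypergeometric tests score functional enrichment of target sets. Basal
    promoter elements (BRE and TATA box) are located by position weight
    matrix scans of TSS-proximal windows with centroid estimation. A seeded
    synthetic-data generator plants annotated genomes, sRNA transcripts,
    negative-binomial replicate counts and promoter motifs with full ground
    truth, so that every stage of the pipeline is testable end to end
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
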