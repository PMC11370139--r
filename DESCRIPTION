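Package: dropgeno
Title: Known-Site SNV Genotyping and Gene-Set Activity Scoring for Droplet Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies droplet scRNA-seq cells as mutated, wildtype or unknown
    at known somatic SNV loci (e.g. CTNNB1 exon 3 drivers) by splice-aware
    pileup of barcoded alignments with cell-barcode (CB) and UMI (UB) tag
    handling, summarises mutation status per cell cluster, computes the
    closed-form heterozygous-fraction expectation implied by per-cell coverage
    depth, and scores per-cell gene-set activity with a rank-based
    recovery-curve AUC (AUCell-style). Includes seeded simulators for barcoded
    alignments with known truth genotypes and for expression matrices with a
    planted active gene set, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rsamtools,
    GenomicRanges,
    IRanges,
    Matrix,
    jsonlite,
    fgsea,
    vcfR,
    withr,
    optparse,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
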