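Package: srnascout
Title: Comparative Discovery of Intergenic Small RNAs in Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for predicting bacterial small non-coding
    RNAs (sRNAs) in intergenic regions (IGRs) by comparative genomics.
    Extracts IGRs from annotated genomes, finds cross-genome conserved
    segments by exact Smith-Waterman local alignment with Karlin-Altschul
    E-values, screens conserved blocks for stable and conserved RNA secondary
    structure (minimum-free-energy folding, dinucleotide-shuffle z-scores,
    structure conservation index, covariation evidence), attaches sigma-70
    promoter and Rho-independent terminator evidence, labels known RNA
    families against a reference library, validates candidates against
    strand-specific RNA-seq coverage with RPKM and condition ratios, predicts
    mRNA targets by seed-anchored antisense hybridization, and summarises
    target function by hypergeometric GO enrichment. Includes a synthetic
    multi-genome generator with planted structured elements and full ground
    truth so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    tools,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
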