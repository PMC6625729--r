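Package: secretescan
Title: Detection and Manipulation of Pyrimidine-Periodic SECReTE Motifs in Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects SECReTE elements, uninterrupted runs of nucleotide triplets
    carrying a pyrimidine (or another two-letter nucleotide class) at a fixed
    triplet position, in coding sequences and untranslated regions of mRNA.
    Quantifies their enrichment in secretome versus non-secretome gene sets
    (gene-set fractions, chi-squared tests with FDR correction, ROC/AUC
    threshold selection), assesses dependence on codon usage by codon-shuffle
    permutation Z-scores, characterises motif region and positional
    distributions, RRY purity and pyrimidine content, excises
    transmembrane-domain and signal-sequence coding regions before rescanning,
    and performs synonymous (+)/(-)SECReTE recoding of coding sequences with
    codon adaptation index bookkeeping. Includes a seeded synthetic
    transcriptome generator with planted motifs and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
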