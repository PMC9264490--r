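Package: denovotx
Title: Reference-Free Transcript Clustering, Error Correction and
    Quantification for Noisy Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs and quantifies a transcriptome directly from
    error-prone long cDNA/dRNA reads (e.g. Oxford Nanopore), without a
    reference genome or annotation.  Reads are clustered into gene-level
    groups with a greedy two-step k-mer similarity (bit-vector screen plus
    a longest-increasing-subsequence chain score), split into transcript
    isoform clusters by the variance of gap-length differences along the
    k-mer chain, error-corrected by block-wise multiple sequence alignment
    with quality-gated consensus correction, and polished into consensus
    transcripts with read-count abundances.  Includes a Nanopore-like read
    simulator with truth labels and the evaluation metrics used to assess
    clustering (adjusted Rand index, homogeneity, completeness, V-measure)
    and exon-intron structure accuracy (recall, precision, read-precision
    over introns, intron chains and exons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    rtracklayer,
    mclust,
    jsonlite,
    optparse
SystemRequirements: MAFFT (the 'mafft' executable on the PATH) for
    multiple sequence alignment; an alternative engine can be plugged in.
Config/testthat/edition: 3
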