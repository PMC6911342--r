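Package: phloemir
Title: Discovery of miRNA Precursors in Tissue Transcriptomes by Local Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting pri-miRNA (miRNA precursor) sequences in
    assembled tissue transcriptomes and deciding which are selectively present
    in one tissue (e.g. phloem sap) versus another (e.g. leaf). Implements a
    Smith-Waterman homology screen with Karlin-Altschul E-value statistics, a
    k-mer seeded read mapper, per-base coverage profiles with the average
    coverage (AC) and local coverage (LC) abundance statistics, LC-based
    candidate selection with Shapiro-Wilk distribution characterisation,
    paired-tissue comparison with mobility classification, diagnosis of
    chimeric assembly artifacts via ORF finding and coverage-peak concordance,
    and in-silico PCR for species-discriminating primer validation. Includes a
    fully ground-truthed synthetic-data generator (hairpin precursor queries,
    two-tissue transcriptomes, chimeric contigs, simulated reads) so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
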