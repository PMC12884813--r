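Package: repclone
Title: Single-Cell Immune Repertoire Clonotyping, Diversity and Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis pipeline for paired-chain single-cell TCR and BCR
    repertoires: contig parsing (10x filtered-contig CSV and AIRR rearrangement
    TSV dialects), chain pairing and quality filtering, strict TCR clonotype
    calling, BCR clonotype grouping by normalized Levenshtein similarity of
    CDR3 nucleotide sequences with shared V-gene usage, repertoire diversity
    statistics (Shannon entropy, clonal-expansion homeostasis bins, Lorenz
    curves and Gini index), pathogen-associated TCR annotation against a CDR3
    reference table, somatic-hypermutation quantification against germline V
    segments, CD45 isoform probability aggregation (CD45RA/CD45RO), group
    comparisons (Mann-Whitney, Kruskal-Wallis with Dunn post-hoc), and a
    synthetic-repertoire generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    Biostrings,
    withr,
    generics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
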