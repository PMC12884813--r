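# Gene-segment name pools used by the repertoire simulator. These are
# synthetic fixture lists shaped like human V(D)J nomenclature; the heavy and
# light V names match the synthetic germline FASTA shipped in inst/extdata.

trav_genes <- sprintf("TRAV%d", 1:30)
traj_genes <- sprintf("TRAJ%d", 1:40)
trbv_genes <- sprintf("TRBV%d", 1:25)
trbd_genes <- c("TRBD1", "TRBD2")
trbj_genes <- sprintf("TRBJ%d-%d", rep(1:2, each = 6), rep(1:6, 2))
trbc_genes <- c("TRBC1", "TRBC2")

ighv_genes <- sprintf("IGHV-S%02d", 1:12)
ighd_genes <- sprintf("IGHD%d", 1:6)
ighj_genes <- sprintf("IGHJ%d", 1:6)
ighc_genes <- c("IGHM", "IGHD", "IGHG1", "IGHG2", "IGHA1")
igkv_genes <- sprintf("IGKV-S%02d", 1:6)
igkj_genes <- sprintf("IGKJ%d", 1:5)
iglv_genes <- sprintf("IGLV-S%02d", 1:6)
iglj_genes <- sprintf("IGLJ%d", 1:3)

# sense codons (no stops) for random in-frame CDR3 generation
sense_codons <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

# fixed back-translation table: lexicographically first codon per amino acid,
# so amino-acid-level matches are exact while nucleotide keys stay distinct
# through the non-CDR3 gene calls
backtranslate_table <- local({
  gc <- Biostrings::GENETIC_CODE
  split_codons <- split(names(gc), gc)
  vapply(split_codons, function(x) sort(x)[1], character(1))
})

#' Back-translate an amino-acid sequence with a fixed codon table
#'
#' Uses the lexicographically first codon for every amino acid, so a given
#' peptide always back-translates to the same nucleotide sequence.
#'
#' @param aa Amino-acid string(s).
#' @return DNA string(s).
#' @export
backtranslate <- function(aa) {
  vapply(strsplit(str_to_upper(aa), "", fixed = TRUE), function(chars) {
    bad <- setdiff(chars, names(backtranslate_table))
    if (length(bad) > 0) {
      abort(sprintf("cannot back-translate residue(s): %s",
                    paste(bad, collapse = ", ")),
            class = "repclone_parameter_error")
    }
    paste(backtranslate_table[chars], collapse = "")
  }, character(1))
}

#' Bundled synthetic pathogen-associated CDR3 database
#'
#' A small synthetic reference table in the VDJdb/McPAS column layout,
#' shipped for simulation and testing; it is not derived from any real
#' database release.
#'
#' @return Tibble as from [read_pathogen_db()].
#' @export
repclone_pathogen_db <- function() {
  read_pathogen_db(system.file("extdata", "pathogen_db_synthetic.tsv",
                               package = "repclone", mustWork = TRUE))
}

#' Bundled synthetic germline V-segment references
#'
#' Synthetic heavy- and light-chain germline V sequences matching the
#' simulator's gene names; not real IMGT alleles.
#'
#' @return Tibble as from [read_germline_fasta()].
#' @export
repclone_germline <- function() {
  read_germline_fasta(system.file("extdata", "germline_v_synthetic.fasta",
                                  package = "repclone", mustWork = TRUE))
}
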