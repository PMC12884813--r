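#' Read a V(D)J contig table
#'
#' Parses per-chain contig annotations into the package's canonical contig
#' tibble. Two dialects are supported: `"tenx_csv"` (10x Genomics
#' filtered-contig style CSV) and `"airr_tsv"` (AIRR Rearrangement TSV).
#' Dialect differences in column naming are normalized away so downstream
#' code sees a single schema.
#'
#' The canonical contig tibble has columns `barcode`, `sample_id`, `locus`
#' (TRA/TRB/IGH/IGK/IGL), `cdr3_nt`, `cdr3_aa`, `v_gene`, `d_gene`, `j_gene`,
#' `c_gene`, `umi_count`, `read_count`, `productive`, and `sequence` (full
#' contig nucleotide sequence when available, `NA` otherwise). Missing gene
#' calls (`"None"`, empty) become `""`; nucleotide and amino-acid strings are
#' upper-cased. Barcodes are kept verbatim — no suffix stripping — so that
#' joins against transcriptome barcode sets never mismatch silently.
#'
#' @param path Path to the contig table.
#' @param dialect One of `"tenx_csv"`, `"airr_tsv"`.
#' @return A tibble with one row per contig, input row order preserved.
#' @export
read_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  spec <- contig_dialects[[dialect]]
  raw <- if (dialect == "tenx_csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  missing_cols <- setdiff(unname(spec), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("contig table %s is missing mandatory %s column(s): %s",
                  path, dialect, paste(missing_cols, collapse = ", ")),
          class = "repclone_format_error")
  }
  out <- tibble(
    barcode    = raw[[spec[["barcode"]]]],
    sample_id  = if ("sample_id" %in% names(raw)) raw[["sample_id"]] else NA_character_,
    locus      = str_to_upper(raw[[spec[["locus"]]]]),
    cdr3_nt    = clean_seq(raw[[spec[["cdr3_nt"]]]]),
    cdr3_aa    = clean_seq(raw[[spec[["cdr3_aa"]]]]),
    v_gene     = clean_gene(raw[[spec[["v_gene"]]]]),
    d_gene     = clean_gene(raw[[spec[["d_gene"]]]]),
    j_gene     = clean_gene(raw[[spec[["j_gene"]]]]),
    c_gene     = clean_gene(raw[[spec[["c_gene"]]]]),
    umi_count  = parse_count(raw[[spec[["umi_count"]]]], spec[["umi_count"]]),
    read_count = parse_count(raw[[spec[["read_count"]]]], spec[["read_count"]]),
    productive = parse_flag(raw[[spec[["productive"]]]]),
    sequence   = if ("sequence" %in% names(raw)) clean_seq(raw[["sequence"]]) else NA_character_
  )
  bad_locus <- setdiff(unique(out$locus), vdj_loci)
  if (length(bad_locus) > 0) {
    warn(sprintf("unrecognized locus value(s) dropped: %s",
                 paste(bad_locus, collapse = ", ")))
    out <- filter(out, .data$locus %in% vdj_loci)
  }
  out
}

#' Write a contig tibble in a supported dialect
#'
#' Inverse of [read_contigs()]: round-tripping a contig tibble through either
#' dialect reproduces it exactly.
#'
#' @param contigs Canonical contig tibble.
#' @param path Output path.
#' @param dialect One of `"tenx_csv"`, `"airr_tsv"`.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  spec <- contig_dialects[[dialect]]
  out <- tibble(
    !!spec[["barcode"]]    := contigs$barcode,
    sample_id              = contigs$sample_id,
    !!spec[["locus"]]      := contigs$locus,
    !!spec[["cdr3_nt"]]    := contigs$cdr3_nt,
    !!spec[["cdr3_aa"]]    := contigs$cdr3_aa,
    !!spec[["v_gene"]]     := contigs$v_gene,
    !!spec[["d_gene"]]     := contigs$d_gene,
    !!spec[["j_gene"]]     := contigs$j_gene,
    !!spec[["c_gene"]]     := contigs$c_gene,
    !!spec[["umi_count"]]  := contigs$umi_count,
    !!spec[["read_count"]] := contigs$read_count,
    productive             = ifelse(contigs$productive, "TRUE", "FALSE"),
    sequence               = contigs$sequence
  )
  if (dialect == "tenx_csv") readr::write_csv(out, path, progress = FALSE)
  else readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a pathogen-associated CDR3 reference table
#'
#' Reads a VDJdb/McPAS-style TSV with columns `cdr3_aa`, `chain`, `v_gene`,
#' `j_gene`, `epitope`, `pathogen`, `species`. Chain tokens `"TRA"`/`"alpha"`
#' and `"TRB"`/`"beta"` (any case) are normalized to `"alpha"`/`"beta"`.
#'
#' @param path Path to the reference TSV.
#' @return A tibble with one row per reference entry.
#' @export
read_pathogen_db <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("cdr3_aa", "chain", "v_gene", "j_gene", "epitope", "pathogen", "species")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("pathogen database is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "repclone_format_error")
  }
  chain <- normalize_chain(raw$chain)
  out <- tibble(
    cdr3_aa  = str_to_upper(str_trim(raw$cdr3_aa)),
    chain    = chain,
    v_gene   = clean_gene(raw$v_gene),
    j_gene   = clean_gene(raw$j_gene),
    epitope  = raw$epitope %||% "",
    pathogen = raw$pathogen,
    species  = raw$species
  )
  if (nrow(out) > 0 && any(!nzchar(out$cdr3_aa) | is.na(out$cdr3_aa))) {
    abort("pathogen database contains empty cdr3_aa entries",
          class = "repclone_format_error")
  }
  if (nrow(out) > 0 && any(is.na(out$pathogen) | !nzchar(out$pathogen))) {
    abort("pathogen database contains empty pathogen labels",
          class = "repclone_format_error")
  }
  out
}

#' Read a transcriptome barcode table
#'
#' Maps each cell barcode detected in the transcriptome (GEX) data to its
#' sample and group label. Duplicated rows with identical labels are
#' collapsed; a barcode appearing with conflicting labels is an error.
#'
#' @param path TSV with columns `barcode`, `sample_id`, `group`.
#' @return A tibble with one row per unique barcode.
#' @export
read_barcode_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("barcode", "sample_id", "group")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("barcode table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "repclone_format_error")
  }
  out <- distinct(raw[, need])
  dup <- out$barcode[duplicated(out$barcode)]
  if (length(dup) > 0) {
    abort(sprintf("barcode(s) mapped to conflicting sample/group labels: %s",
                  paste(unique(dup), collapse = ", ")),
          class = "repclone_format_error")
  }
  out
}

#' Read germline V-segment references from FASTA
#'
#' @param path FASTA file keyed by V-gene name (first token of each header).
#' @return A tibble with columns `gene_name`, `sequence`.
#' @export
read_germline_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(
    gene_name = vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L),
    sequence  = str_to_upper(as.character(seqs))
  )
}

#' Write germline references as FASTA
#'
#' @param germline Tibble with columns `gene_name`, `sequence`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(germline, path) {
  set <- Biostrings::DNAStringSet(germline$sequence)
  names(set) <- germline$gene_name
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# ---- internal helpers --------------------------------------------------------

vdj_loci <- c("TRA", "TRB", "IGH", "IGK", "IGL")

contig_dialects <- list(
  tenx_csv = c(barcode = "barcode", locus = "chain", cdr3_aa = "cdr3",
               cdr3_nt = "cdr3_nt", v_gene = "v_gene", d_gene = "d_gene",
               j_gene = "j_gene", c_gene = "c_gene", umi_count = "umis",
               read_count = "reads", productive = "productive"),
  airr_tsv = c(barcode = "cell_id", locus = "locus", cdr3_aa = "junction_aa",
               cdr3_nt = "junction", v_gene = "v_call",
               d_gene = "d_call", j_gene = "j_call", c_gene = "c_call",
               umi_count = "duplicate_count", read_count = "consensus_count",
               productive = "productive")
)

clean_gene <- function(x) {
  x <- ifelse(is.na(x) | x %in% c("None", "none", "NA"), "", str_trim(x))
  x
}

clean_seq <- function(x) {
  x <- str_to_upper(str_trim(x))
  ifelse(is.na(x) | !nzchar(x), NA_character_, x)
}

parse_count <- function(x, col) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf("unparseable %s value %s at row %d", col,
                  dQuote(x[bad[1]]), bad[1]),
          class = "repclone_row_error")
  }
  if (any(out < 0, na.rm = TRUE)) {
    abort(sprintf("negative %s value at row %d", col, which(out < 0)[1]),
          class = "repclone_row_error")
  }
  out
}

parse_flag <- function(x) {
  lx <- tolower(str_trim(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "yes", "1")] <- TRUE
  out[lx %in% c("false", "f", "no", "none", "0", "")] <- FALSE
  out
}

normalize_chain <- function(x) {
  lx <- tolower(str_trim(x))
  out <- rep(NA_character_, length(lx))
  out[lx %in% c("tra", "alpha", "a")] <- "alpha"
  out[lx %in% c("trb", "beta", "b")] <- "beta"
  bad <- unique(x[is.na(out) & !is.na(x)])
  if (length(bad) > 0) {
    abort(sprintf("unknown chain token(s) in pathogen database: %s",
                  paste(bad, collapse = ", ")),
          class = "repclone_format_error")
  }
  out
}
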