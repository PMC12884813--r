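#' Resolve multiple chains per locus class down to one
#'
#' When a barcode carries several contigs for the same locus class, only the
#' dominant chain is kept: highest UMI count, ties broken by highest read
#' count, then by lexicographically smallest CDR3 nucleotide sequence so the
#' outcome never depends on input order. Locus classes are TRA, TRB, IGH and
#' light (IGK and IGL compete with each other, so a cell with both kappa and
#' lambda calls keeps the better-supported one).
#'
#' @param contigs Canonical contig tibble (any number of barcodes).
#' @return A contig tibble with at most one row per barcode and locus class.
#' @export
resolve_chains <- function(contigs) {
  if (nrow(contigs) == 0) return(contigs)
  contigs |>
    mutate(chain_class = locus_class(.data$locus)) |>
    group_by(.data$barcode, .data$chain_class) |>
    arrange(desc(.data$umi_count), desc(.data$read_count), .data$cdr3_nt,
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    select(-"chain_class") |>
    arrange(.data$barcode, .data$locus)
}

#' Filter contigs to QC-passing paired cells
#'
#' Applies the three repertoire quality filters: (1) a cell must carry both
#' required chain classes (alpha and beta for T cells; heavy and light for B
#' cells) — single-chain cells are discarded; (2) when a cell has multiple
#' chains of a class, the dominant one is kept (see [resolve_chains()]);
#' (3) only barcodes also detected in the single-cell transcriptome (the
#' `gex_barcodes` table) are retained, which also attaches sample and group
#' labels.
#'
#' @param contigs Canonical contig tibble.
#' @param gex_barcodes Barcode table from [read_barcode_table()] (columns
#'   `barcode`, `sample_id`, `group`).
#' @param cell_class `"T"` or `"B"`.
#' @param require_productive Drop non-productive contigs before pairing
#'   (default `TRUE`).
#' @return A paired-cell tibble with one row per retained cell: `barcode`,
#'   `sample_id`, `group`, `cell_class`, and the two chains in wide form with
#'   prefixes `a_` (TRA or IGH) and `b_` (TRB or light chain).
#' @export
filter_paired_cells <- function(contigs, gex_barcodes,
                                cell_class = c("T", "B"),
                                require_productive = TRUE) {
  cell_class <- match.arg(cell_class)
  allowed <- if (cell_class == "T") c("TRA", "TRB") else c("IGH", "IGK", "IGL")
  n_bad <- sum(!contigs$locus %in% allowed)
  if (n_bad > 0) {
    warn(sprintf("%d contig(s) with loci inconsistent with cell_class=%s ignored",
                 n_bad, cell_class))
  }
  contigs <- filter(contigs, .data$locus %in% allowed)
  if (require_productive) contigs <- filter(contigs, .data$productive)
  resolved <- resolve_chains(contigs) |>
    mutate(chain_class = locus_class(.data$locus))

  a_class <- if (cell_class == "T") "TRA" else "IGH"
  b_class <- if (cell_class == "T") "TRB" else "light"
  chain_cols <- c("locus", "cdr3_nt", "cdr3_aa", "v_gene", "d_gene", "j_gene",
                  "c_gene", "umi_count", "read_count", "sequence")
  a <- resolved |>
    filter(.data$chain_class == a_class) |>
    select("barcode", all_of(chain_cols)) |>
    rename_with(~ paste0("a_", .x), all_of(chain_cols))
  b <- resolved |>
    filter(.data$chain_class == b_class) |>
    select("barcode", all_of(chain_cols)) |>
    rename_with(~ paste0("b_", .x), all_of(chain_cols))

  inner_join(a, b, by = "barcode") |>
    inner_join(gex_barcodes, by = "barcode") |>
    mutate(cell_class = cell_class) |>
    select("barcode", "sample_id", "group", "cell_class", everything()) |>
    arrange(.data$sample_id, .data$barcode)
}

#' Flatten a paired-cell tibble back into contig rows
#'
#' Convenience inverse used to re-apply QC to an already-filtered set (a
#' fixed point of [filter_paired_cells()]) or to serialize pairs.
#'
#' @param pairs Paired-cell tibble from [filter_paired_cells()].
#' @return A canonical contig tibble with two rows per cell.
#' @export
pairs_to_contigs <- function(pairs) {
  chain_cols <- c("locus", "cdr3_nt", "cdr3_aa", "v_gene", "d_gene", "j_gene",
                  "c_gene", "umi_count", "read_count", "sequence")
  one <- function(prefix) {
    out <- pairs |> select("barcode", "sample_id", all_of(paste0(prefix, chain_cols)))
    names(out) <- c("barcode", "sample_id", chain_cols)
    out
  }
  bind_rows(one("a_"), one("b_")) |>
    mutate(productive = TRUE) |>
    select("barcode", "sample_id", "locus", "cdr3_nt", "cdr3_aa", "v_gene",
           "d_gene", "j_gene", "c_gene", "umi_count", "read_count",
           "productive", "sequence") |>
    arrange(.data$barcode, .data$locus)
}

locus_class <- function(locus) {
  ifelse(locus %in% c("IGK", "IGL"), "light", locus)
}
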