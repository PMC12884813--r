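#' Annotate T cells against a pathogen-associated CDR3 database
#'
#' A cell is annotated with a pathogen when the amino-acid CDR3 of either
#' chain exactly matches a database entry for that pathogen on the same
#' chain: TRA CDR3 against alpha-chain entries, TRB CDR3 against beta-chain
#' entries (case-insensitive). This is single-chain matching — one matching
#' chain suffices — so annotations indicate pathogen association, not proven
#' paired-chain specificity. Matching is exact by default; `max_mismatch = 1`
#' enables Hamming-distance-1 matching for sensitivity analyses.
#'
#' @param pairs Paired-cell tibble of T cells.
#' @param db Pathogen reference tibble from [read_pathogen_db()].
#' @param species Restrict the database to this host species
#'   (default `"HomoSapiens"`).
#' @param require_v_gene When `TRUE`, a database entry with a non-empty
#'   `v_gene` only matches cells whose corresponding V call equals it.
#' @param max_mismatch 0 (exact, default) or 1 (Hamming-1 on equal-length
#'   CDR3s).
#' @return A tibble with one row per cell: `barcode`, `sample_id`, `group`,
#'   `matched_chain` (`"alpha"`, `"beta"`, `"both"` or `"none"`) and a
#'   list-column `pathogens` of matched pathogen labels. The long per-match
#'   table (cell x database entry) is attached as attribute `"matches"`.
#' @export
annotate_cells <- function(pairs, db, species = "HomoSapiens",
                           require_v_gene = FALSE, max_mismatch = 0) {
  stopifnot(all(pairs$cell_class == "T"))
  if (nrow(db) == 0) {
    abort("pathogen database is empty", class = "repclone_parameter_error")
  }
  if (!max_mismatch %in% c(0, 1)) {
    abort("max_mismatch must be 0 or 1", class = "repclone_parameter_error")
  }
  db <- filter(db, .data$species == !!species)

  match_one_chain <- function(chain_label, cdr3, v_call) {
    entries <- filter(db, .data$chain == chain_label)
    if (nrow(entries) == 0 || nrow(pairs) == 0) {
      return(tibble(row = integer(0), pathogen = character(0),
                    epitope = character(0), db_cdr3 = character(0),
                    chain = character(0)))
    }
    cells <- tibble(row = seq_along(cdr3), cdr3_aa = str_to_upper(cdr3),
                    v_call = v_call)
    if (max_mismatch == 0) {
      hits <- inner_join(cells, entries, by = "cdr3_aa",
                         relationship = "many-to-many")
    } else {
      hits <- cross_join(cells, rename(entries, db_cdr3_aa = "cdr3_aa")) |>
        filter(nchar(.data$cdr3_aa) == nchar(.data$db_cdr3_aa)) |>
        filter(levenshtein(.data$cdr3_aa, .data$db_cdr3_aa) <= 1) |>
        rename(cdr3_aa_db = "db_cdr3_aa")
    }
    if (require_v_gene) {
      hits <- filter(hits, !nzchar(.data$v_gene) | .data$v_gene == .data$v_call)
    }
    db_cdr3 <- if (max_mismatch == 0) hits$cdr3_aa else hits$cdr3_aa_db
    tibble(row = hits$row, pathogen = hits$pathogen, epitope = hits$epitope,
           db_cdr3 = db_cdr3, chain = chain_label)
  }

  matches <- bind_rows(
    match_one_chain("alpha", pairs$a_cdr3_aa, pairs$a_v_gene),
    match_one_chain("beta", pairs$b_cdr3_aa, pairs$b_v_gene)
  )

  per_cell <- matches |>
    group_by(.data$row) |>
    summarise(
      matched_chain = if (all(c("alpha", "beta") %in% .data$chain)) "both"
                      else .data$chain[1],
      pathogens = list(sort(unique(.data$pathogen))),
      .groups = "drop"
    )
  out <- pairs |>
    select("barcode", "sample_id", "group") |>
    mutate(row = row_number()) |>
    left_join(per_cell, by = "row") |>
    mutate(matched_chain = coalesce(.data$matched_chain, "none")) |>
    select(-"row")
  out$pathogens[vapply(out$pathogens, is.null, logical(1))] <- list(character(0))
  long <- matches |>
    mutate(barcode = pairs$barcode[.data$row],
           sample_id = pairs$sample_id[.data$row]) |>
    select("barcode", "sample_id", "chain", "pathogen", "epitope", "db_cdr3")
  attr(out, "matches") <- long
  out
}

#' Per-pathogen repertoire metrics
#'
#' For each sample and pathogen: the percentage of QC-passing T cells
#' annotated with the pathogen, and the Shannon diversity of the annotated
#' subset, computed over that subset's clonotype frequencies renormalized to
#' sum to 1. Diversity is `NA` when no cell matched. A cell matching several
#' pathogens counts once for each, so percentages may sum above 100 across
#' pathogens.
#'
#' @param annotations Output of [annotate_cells()].
#' @param assignments Cell-level clonotype assignments from
#'   [call_clonotypes()] (same cells).
#' @param pathogens Pathogen labels to report; default all labels present in
#'   the annotations. An unknown label is an error.
#' @return Tibble `sample_id`, `group`, `pathogen`, `n_matched`, `pct`,
#'   `diversity`.
#' @export
pathogen_metrics <- function(annotations, assignments, pathogens = NULL) {
  known <- sort(unique(unlist(annotations$pathogens)))
  if (is.null(pathogens)) pathogens <- known
  unknown <- setdiff(pathogens, known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown pathogen label(s): %s (known: %s)",
                  paste(unknown, collapse = ", "),
                  paste(known, collapse = ", ")),
          class = "repclone_parameter_error")
  }
  totals <- count(annotations, .data$sample_id, .data$group, name = "n_total")
  cell_clone <- select(assignments, "barcode", "sample_id", "clonotype_id")

  purrr::map(pathogens, function(p) {
    hit <- annotations |>
      filter(purrr::map_lgl(.data$pathogens, ~ p %in% .x)) |>
      select("barcode", "sample_id", "group")
    per_sample <- totals |>
      left_join(count(hit, .data$sample_id, name = "n_matched"), by = "sample_id") |>
      mutate(n_matched = coalesce(.data$n_matched, 0L),
             pct = 100 * .data$n_matched / .data$n_total,
             pathogen = p)
    div <- hit |>
      inner_join(cell_clone, by = c("barcode", "sample_id")) |>
      group_by(.data$sample_id) |>
      summarise(diversity = {
        f <- as.numeric(table(.data$clonotype_id))
        shannon_entropy(f / sum(f))
      }, .groups = "drop")
    per_sample |>
      left_join(div, by = "sample_id") |>
      select("sample_id", "group", "pathogen", "n_matched", "pct", "diversity")
  }) |>
    list_rbind() |>
    arrange(.data$pathogen, .data$sample_id)
}
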