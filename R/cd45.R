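#' CD45 isoform exon-inclusion patterns
#'
#' The six CD45 isoforms distinguished at the 5' end of the gene, defined by
#' which of the variable exons 4 (A), 5 (B) and 6 (C) they include. Exon 7 is
#' constitutive and present in all of them.
#'
#' @format Named list of integer vectors (included variable exons).
#' @export
cd45_isoform_exons <- list(
  RAX   = c(4L),
  RABX  = c(4L, 5L),
  RBX   = c(5L),
  RBCX  = c(5L, 6L),
  RABCX = c(4L, 5L, 6L),
  RX    = integer(0)
)

#' Per-read isoform probabilities from exon evidence
#'
#' Converts the exon-overlap evidence of one read into a probability vector
#' over the six CD45 isoforms: unit mass is split uniformly over all isoforms
#' whose exon-inclusion pattern is consistent with every observed presence
#' and absence. A read with no evidence is uninformative (1/6 each); evidence
#' incompatible with every isoform (e.g. absence of the constitutive exon 7)
#' yields an all-zero vector with a warning.
#'
#' @param exons_present,exons_absent Disjoint integer subsets of `{4,5,6,7}`.
#' @param prior Optional named weights over isoforms (default uniform).
#' @return Named numeric vector over `RAX, RABX, RBX, RBCX, RABCX, RX`.
#' @export
isoform_probs_from_exons <- function(exons_present = integer(0),
                                     exons_absent = integer(0),
                                     prior = NULL) {
  exons_present <- as.integer(exons_present)
  exons_absent <- as.integer(exons_absent)
  if (length(intersect(exons_present, exons_absent)) > 0) {
    abort("exons_present and exons_absent must be disjoint",
          class = "repclone_parameter_error")
  }
  if (!all(c(exons_present, exons_absent) %in% 4:7)) {
    abort("exon evidence must be within exons 4-7",
          class = "repclone_parameter_error")
  }
  iso <- names(cd45_isoform_exons)
  compatible <- vapply(cd45_isoform_exons, function(inc) {
    has <- c(inc, 7L)  # exon 7 is constitutive
    all(exons_present %in% has) && !any(exons_absent %in% has)
  }, logical(1))
  w <- if (is.null(prior)) setNames(rep(1, length(iso)), iso) else prior[iso]
  probs <- setNames(numeric(length(iso)), iso)
  if (!any(compatible)) {
    warn("exon evidence incompatible with every CD45 isoform; returning zeros")
    return(probs)
  }
  probs[compatible] <- w[compatible] / sum(w[compatible])
  probs
}

#' Read a per-read CD45 isoform evidence table
#'
#' Accepts either pre-computed per-read probabilities (columns `barcode`,
#' `read_id`, `RAX`, `RABX`, `RBX`, `RBCX`, `RABCX`, `RX`, e.g. from an
#' upstream isoform quantifier) or raw exon evidence (columns `barcode`,
#' `read_id`, `exons_present`, `exons_absent` as comma-separated exon
#' numbers), which is converted with [isoform_probs_from_exons()].
#'
#' @param path TSV path.
#' @return Tibble `barcode`, `read_id`, and the six isoform probability
#'   columns.
#' @export
read_isoform_reads <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  iso <- names(cd45_isoform_exons)
  if (all(iso %in% names(raw))) {
    out <- select(raw, "barcode", "read_id", all_of(iso)) |>
      mutate(across(all_of(iso), as.numeric))
    if (anyNA(out[iso])) {
      abort(sprintf("unparseable isoform probability at row %d",
                    which(rowSums(is.na(out[iso])) > 0)[1]),
            class = "repclone_row_error")
    }
  } else if (all(c("exons_present", "exons_absent") %in% names(raw))) {
    parse_exons <- function(x) {
      lapply(str_split(replace_na(as.character(x), ""), ","),
             function(v) as.integer(v[nzchar(v)]))
    }
    pres <- parse_exons(raw$exons_present)
    abs_ <- parse_exons(raw$exons_absent)
    probs <- purrr::map2(pres, abs_, isoform_probs_from_exons)
    out <- bind_cols(select(raw, "barcode", "read_id"),
                     as_tibble(do.call(rbind, probs)))
  } else {
    abort("isoform table needs either the six isoform probability columns or exons_present/exons_absent",
          class = "repclone_format_error")
  }
  bad <- rowSums(out[iso]) > 1 + 1e-9 | apply(out[iso] < 0, 1, any)
  if (any(bad)) {
    abort(sprintf("invalid isoform probabilities at row %d", which(bad)[1]),
          class = "repclone_row_error")
  }
  out
}

#' Aggregate CD45RA/CD45RO probabilities per barcode
#'
#' The CD45RA signal of a read is the summed probability of the
#' exon-4-containing isoforms RAX, RABX and RABCX; the CD45RO signal is the
#' probability of RX (no variable exon). Read-level signals are summed per
#' cell barcode to give the totals used downstream.
#'
#' @param reads Per-read probability tibble (see [read_isoform_reads()]).
#' @return Tibble `barcode`, `RA`, `RO`, one row per barcode.
#' @export
aggregate_ra_ro <- function(reads) {
  reads |>
    group_by(.data$barcode) |>
    summarise(RA = sum(.data$RAX + .data$RABX + .data$RABCX),
              RO = sum(.data$RX), .groups = "drop") |>
    arrange(.data$barcode)
}
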