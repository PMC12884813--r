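#' Count somatic mutations against a germline V segment
#'
#' Aligns an observed V-region nucleotide sequence to its germline reference
#' with a global end-free (overlap) alignment — match +1, mismatch -1, linear
#' gap -2, terminal gaps free — and counts mutations within the aligned
#' region: every substitution plus one event per contiguous internal indel
#' run (so a 3-nt insertion counts once, not three times). The aligned length
#' is the number of germline positions covered by the alignment, and the SHM
#' frequency reported elsewhere is `100 * mutation_count / aligned_length`.
#'
#' @param observed_v_nt Observed V-region DNA sequence.
#' @param germline_seq Germline V-segment DNA sequence.
#' @return A list with `mutation_count` and `aligned_length`.
#' @export
count_mutations <- function(observed_v_nt, germline_seq) {
  stopifnot(nzchar(observed_v_nt), nzchar(germline_seq))
  res <- align_to_germline(observed_v_nt, germline_seq)
  list(mutation_count = res$mutation_count[1],
       aligned_length = res$aligned_length[1])
}

#' Per-cell somatic hypermutation profile
#'
#' Computes mutation counts and SHM frequency for every B cell, by default on
#' the heavy chain (the dominant SHM signal; `chain = "light"` uses the
#' light chain). Each cell's observed V-region sequence (`a_sequence` /
#' `b_sequence`, carried through from the contig table) is aligned to the
#' germline reference matching its V-gene call.
#'
#' @param pairs Paired-cell tibble of B cells with observed sequences.
#' @param germline Germline reference tibble from [read_germline_fasta()].
#' @param chain `"heavy"` (default) or `"light"`.
#' @return Tibble with one row per cell: `barcode`, `sample_id`, `group`,
#'   `locus`, `v_gene`, `mutation_count`, `aligned_length`, `frequency`
#'   (percent).
#' @export
shm_profile <- function(pairs, germline, chain = c("heavy", "light")) {
  chain <- match.arg(chain)
  pre <- if (chain == "heavy") "a_" else "b_"
  obs <- pairs[[paste0(pre, "sequence")]]
  vg <- pairs[[paste0(pre, "v_gene")]]
  loc <- pairs[[paste0(pre, "locus")]]
  if (any(is.na(obs) | !nzchar(obs))) {
    abort("observed V-region sequences are missing for some cells; SHM needs the contig `sequence` column",
          class = "repclone_parameter_error")
  }
  missing_genes <- setdiff(unique(vg), germline$gene_name)
  if (length(missing_genes) > 0) {
    abort(sprintf("V gene(s) absent from germline reference: %s",
                  paste(missing_genes, collapse = ", ")),
          class = "repclone_parameter_error")
  }
  ref <- setNames(germline$sequence, germline$gene_name)
  out <- tibble(barcode = pairs$barcode, sample_id = pairs$sample_id,
                group = pairs$group, locus = loc, v_gene = vg,
                mutation_count = NA_integer_, aligned_length = NA_integer_)
  # align per germline gene so each pairwiseAlignment call is vectorized
  for (g in unique(vg)) {
    idx <- which(vg == g)
    res <- align_to_germline(obs[idx], ref[[g]])
    out$mutation_count[idx] <- res$mutation_count
    out$aligned_length[idx] <- res$aligned_length
  }
  mutate(out, frequency = 100 * .data$mutation_count / .data$aligned_length)
}

#' Per-sample SHM summary
#'
#' Median, interquartile range and mean of the per-cell SHM frequency for
#' each sample. Samples with zero cells are absent by construction.
#'
#' @param shm Per-cell table from [shm_profile()].
#' @return Tibble `sample_id`, `group`, `n_cells`, `median_freq`, `iqr_freq`,
#'   `mean_freq`, `mean_count`.
#' @export
shm_summary <- function(shm) {
  shm |>
    group_by(.data$sample_id, .data$group) |>
    summarise(
      n_cells = n(),
      median_freq = median(.data$frequency),
      iqr_freq = stats::IQR(.data$frequency),
      mean_freq = mean(.data$frequency),
      mean_count = mean(.data$mutation_count),
      .groups = "drop"
    )
}

# ---- internal ----------------------------------------------------------------

# Overlap alignment of one or more observed sequences against one germline.
# Returns substitutions + internal indel events, and the number of germline
# positions inside the aligned region.
align_to_germline <- function(observed, germline_seq) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(observed),
    subject = Biostrings::DNAString(germline_seq),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2
  )
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  n <- length(pat)
  mut <- integer(n)
  alen <- integer(n)
  for (i in seq_len(n)) {
    p <- strsplit(pat[i], "", fixed = TRUE)[[1]]
    s <- strsplit(sub[i], "", fixed = TRUE)[[1]]
    gap <- p == "-" | s == "-"
    subs <- sum(!gap & p != s)
    indel_events <- sum(rle(gap)$values)
    mut[i] <- subs + indel_events
    alen[i] <- sum(s != "-")
  }
  list(mutation_count = mut, aligned_length = alen)
}
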