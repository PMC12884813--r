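#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' transforming `s` into `t`. Vectorized over pairs (arguments recycled).
#'
#' @param s,t Character vectors.
#' @return Integer vector of distances.
#' @export
levenshtein <- function(s, t) {
  cpp_levenshtein(as.character(s), as.character(t))
}

#' Normalized CDR3 similarity for BCR grouping
#'
#' The similarity used to group B-cell receptors derived from a common
#' progenitor:
#' `1 - levenshtein(s, t) / ((nchar(s) + nchar(t)) / 2)`.
#' It equals 1 exactly when the sequences are identical and can be negative
#' for very dissimilar sequences of unequal length; no clamping is applied.
#'
#' @param s,t CDR3 nucleotide sequences (non-empty). Vectorized.
#' @return Numeric vector of similarities.
#' @export
bcr_similarity <- function(s, t) {
  s <- as.character(s); t <- as.character(t)
  if (any(!nzchar(s)) || any(!nzchar(t)) || anyNA(s) || anyNA(t)) {
    abort("bcr_similarity is undefined for empty sequences",
          class = "repclone_parameter_error")
  }
  1 - levenshtein(s, t) / ((nchar(s) + nchar(t)) / 2)
}

#' Strict TCR clonotype key
#'
#' Builds the strict clonotype key for each T cell: the ordered concatenation
#' of V, D, J and C gene calls plus the CDR3 nucleotide sequence for the
#' alpha chain, followed by the same for the beta chain. Two cells belong to
#' the same clonotype iff their keys are equal; any single-base CDR3
#' difference or any differing gene call separates them. Missing D/C calls
#' are empty strings, so absent calls compare equal to absent calls.
#'
#' @param pairs Paired-cell tibble of T cells.
#' @return Character vector of keys, one per row of `pairs`.
#' @export
tcr_clonotype_key <- function(pairs) {
  stopifnot(all(pairs$cell_class == "T"))
  paste(
    pairs$a_v_gene, pairs$a_d_gene, pairs$a_j_gene, pairs$a_c_gene, pairs$a_cdr3_nt,
    pairs$b_v_gene, pairs$b_d_gene, pairs$b_j_gene, pairs$b_c_gene, pairs$b_cdr3_nt,
    sep = ";"
  )
}

#' Call clonotypes on paired cells
#'
#' Assigns a clonotype to every QC-passing cell. T cells use the strict key
#' ([tcr_clonotype_key()]): identical CDR3 nucleotide sequences and identical
#' V, D, J and C gene calls on both chains. B cells are grouped by similarity
#' clustering ([cluster_bcr()]): within each chain class, chains sharing a V
#' gene and reaching [bcr_similarity()] `>= threshold` are linked, clusters
#' are the connected components (single linkage), and a cell's clonotype is
#' the pair of its heavy- and light-chain clusters (or heavy only, with
#' `bcr_chains = "heavy"`).
#'
#' Clonotype identifiers are assigned per sample, deterministically, by
#' descending clone size then lexicographic key.
#'
#' @param pairs Paired-cell tibble from [filter_paired_cells()].
#' @param method `"tcr_strict"` or `"bcr_cluster"`; defaults by cell class.
#' @param threshold BCR similarity threshold in (0, 1], default 0.85.
#' @param bcr_chains `"both"` (default) or `"heavy"`.
#' @return The input tibble with columns `clonotype_id` and `clonotype_key`
#'   appended.
#' @export
call_clonotypes <- function(pairs, method = NULL, threshold = 0.85,
                            bcr_chains = c("both", "heavy")) {
  bcr_chains <- match.arg(bcr_chains)
  if (is.null(method)) {
    method <- if (all(pairs$cell_class == "T")) "tcr_strict" else "bcr_cluster"
  }
  method <- match.arg(method, c("tcr_strict", "bcr_cluster"))
  if (nrow(pairs) == 0) {
    return(mutate(pairs, clonotype_id = character(0), clonotype_key = character(0)))
  }
  if (method == "tcr_strict") {
    keyed <- mutate(pairs, clonotype_key = tcr_clonotype_key(pairs))
  } else {
    keyed <- cluster_bcr(pairs, threshold = threshold, chains = bcr_chains)
  }
  keyed |>
    group_by(.data$sample_id) |>
    group_modify(~ assign_clonotype_ids(.x, .y$sample_id)) |>
    ungroup() |>
    arrange(.data$sample_id, .data$barcode)
}

#' Cluster BCRs by normalized Levenshtein similarity
#'
#' Within each sample and chain class, two chains are linked iff they share
#' the V gene call and their CDR3 nucleotide similarity is at least
#' `threshold`; clusters are the connected components of that graph
#' (transitive closure / single linkage), so a chain joins a clone if it is
#' close to any member — the behaviour expected of lineages diversified by
#' somatic hypermutation, where intermediate mutants bridge distant ones.
#'
#' @param pairs Paired-cell tibble of B cells.
#' @param threshold Similarity threshold in (0, 1].
#' @param chains `"both"`: clonotype = (heavy cluster, light cluster);
#'   `"heavy"`: heavy-chain cluster only.
#' @return `pairs` with a `clonotype_key` column describing the cluster pair.
#' @export
cluster_bcr <- function(pairs, threshold = 0.85, chains = c("both", "heavy")) {
  chains <- match.arg(chains)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    abort("threshold must be a single number in (0, 1]",
          class = "repclone_parameter_error")
  }
  stopifnot(all(pairs$cell_class == "B"))
  heavy <- chain_clusters(pairs$sample_id, pairs$a_v_gene, pairs$a_cdr3_nt, threshold)
  key <- paste0("H", heavy)
  if (chains == "both") {
    light <- chain_clusters(pairs$sample_id, pairs$b_v_gene, pairs$b_cdr3_nt, threshold)
    key <- paste0(key, ";L", light)
  }
  mutate(pairs, clonotype_key = key)
}

#' Summarise clonotype assignments
#'
#' Collapses a cell-level clonotype assignment into one row per clonotype and
#' sample, with cell counts and relative frequencies X = size / total paired
#' cells in that sample (frequencies sum to 1 within each sample).
#'
#' @param assignments Output of [call_clonotypes()].
#' @return Tibble with columns `sample_id`, `group`, `clonotype_id`,
#'   `clonotype_key`, `size`, `freq`, sorted by descending size within sample.
#' @export
summarise_clonotypes <- function(assignments) {
  assignments |>
    group_by(.data$sample_id, .data$group, .data$clonotype_id,
             clonotype_key = .data$clonotype_key) |>
    summarise(size = n(), .groups = "drop") |>
    group_by(.data$sample_id) |>
    mutate(freq = .data$size / sum(.data$size)) |>
    ungroup() |>
    arrange(.data$sample_id, desc(.data$size), .data$clonotype_id)
}

# ---- internal ----------------------------------------------------------------

# Connected components of the similarity graph, computed per (sample, V gene)
# block: chains with different V genes can never be linked, so the quadratic
# distance matrix is only built within blocks.
chain_clusters <- function(sample_id, v_gene, cdr3_nt, threshold) {
  n <- length(cdr3_nt)
  block <- paste(sample_id, v_gene, sep = "\r")
  comp <- integer(n)
  offset <- 0L
  for (idx in split(seq_len(n), block)) {
    seqs <- cdr3_nt[idx]
    if (length(idx) == 1L) {
      comp[idx] <- offset + 1L
      offset <- offset + 1L
      next
    }
    d <- cpp_levenshtein_matrix(seqs)
    len <- nchar(seqs)
    denom <- outer(len, len, `+`) / 2
    sim <- 1 - d / denom
    adj <- sim >= threshold
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    memb <- igraph::components(g)$membership
    comp[idx] <- offset + memb
    offset <- offset + max(memb)
  }
  # re-key components by sample + block-local id so keys are readable
  match(paste(sample_id, comp), unique(paste(sample_id, comp)))
}

assign_clonotype_ids <- function(cells, sample_id) {
  tab <- cells |>
    count(.data$clonotype_key, name = "size") |>
    arrange(desc(.data$size), .data$clonotype_key) |>
    mutate(clonotype_id = sprintf("%s_CT%05d", sample_id, row_number()))
  cells |>
    left_join(select(tab, "clonotype_key", "clonotype_id"), by = "clonotype_key")
}
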