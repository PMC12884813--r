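# Independent oracles used to cross-check the implementation. These are
# deliberately naive/brute-force and share no code with the package.

# full dynamic-programming edit distance, plain R
oracle_levenshtein <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0) return(nb)
  if (nb == 0) return(na)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  d <- matrix(0L, na + 1, nb + 1)
  d[, 1] <- 0:na
  d[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d[i + 1, j + 1] <- min(d[i, j] + (av[i] != bv[j]),
                             d[i, j + 1] + 1L,
                             d[i + 1, j] + 1L)
    }
  }
  d[na + 1, nb + 1]
}

# brute-force single-linkage clustering: all-pairs similarity matrix and
# union-find transitive closure
oracle_bcr_clusters <- function(v_gene, cdr3, threshold) {
  n <- length(cdr3)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (v_gene[i] != v_gene[j]) next
      d <- utils::adist(cdr3[i], cdr3[j])[1, 1]
      sim <- 1 - d / ((nchar(cdr3[i]) + nchar(cdr3[j])) / 2)
      if (sim >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# mean-absolute-difference Gini
oracle_gini <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, `-`))) / (2 * n^2 * mean(x))
}

# exact two-sided Mann-Whitney p by enumerating every rank assignment
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# adjusted Rand index between two labelings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

random_dna <- function(n, min_len = 6, max_len = 20) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(min_len:max_len, 1),
                 replace = TRUE), collapse = "")
  }, character(1))
}

# minimal contig tibble builder for unit tests
make_contig <- function(barcode, locus, cdr3_nt = "TGTGCAGCA", umi = 5L,
                        reads = 100L, v = "V1", d = "", j = "J1", c = "C1",
                        productive = TRUE, sample_id = "S1", sequence = NA_character_) {
  tibble::tibble(
    barcode = barcode, sample_id = sample_id, locus = locus,
    cdr3_nt = cdr3_nt,
    cdr3_aa = "CAA", v_gene = v, d_gene = d, j_gene = j, c_gene = c,
    umi_count = as.integer(umi), read_count = as.integer(reads),
    productive = productive, sequence = sequence
  )
}

make_barcode_table <- function(barcodes, sample_id = "S1", group = "HD") {
  tibble::tibble(barcode = barcodes, sample_id = sample_id, group = group)
}

# minimal paired T cell for clonotype/pathogen tests
make_tcell <- function(barcode, a_cdr3_nt = "TGTGCT", b_cdr3_nt = "TGTGCA",
                       a_cdr3_aa = "CA", b_cdr3_aa = "CA",
                       a_v = "TRAV1", b_v = "TRBV1", b_d = "TRBD1",
                       sample_id = "S1", group = "HD") {
  tibble::tibble(
    barcode = barcode, sample_id = sample_id, group = group, cell_class = "T",
    a_locus = "TRA", a_cdr3_nt = a_cdr3_nt, a_cdr3_aa = a_cdr3_aa,
    a_v_gene = a_v, a_d_gene = "", a_j_gene = "TRAJ1", a_c_gene = "TRAC",
    a_umi_count = 5L, a_read_count = 100L, a_sequence = NA_character_,
    b_locus = "TRB", b_cdr3_nt = b_cdr3_nt, b_cdr3_aa = b_cdr3_aa,
    b_v_gene = b_v, b_d_gene = b_d, b_j_gene = "TRBJ1-1", b_c_gene = "TRBC1",
    b_umi_count = 5L, b_read_count = 100L, b_sequence = NA_character_
  )
}

# minimal paired B cell
make_bcell <- function(barcode, h_cdr3, l_cdr3 = "TGTCAACAA", h_v = "IGHV-S01",
                       l_v = "IGKV-S01", sample_id = "S1", group = "HD",
                       h_seq = NA_character_) {
  tibble::tibble(
    barcode = barcode, sample_id = sample_id, group = group, cell_class = "B",
    a_locus = "IGH", a_cdr3_nt = h_cdr3, a_cdr3_aa = "CAA",
    a_v_gene = h_v, a_d_gene = "IGHD1", a_j_gene = "IGHJ1", a_c_gene = "IGHM",
    a_umi_count = 5L, a_read_count = 100L, a_sequence = h_seq,
    b_locus = "IGK", b_cdr3_nt = l_cdr3, b_cdr3_aa = "CQQ",
    b_v_gene = l_v, b_d_gene = "", b_j_gene = "IGKJ1", b_c_gene = "IGKC",
    b_umi_count = 5L, b_read_count = 100L, b_sequence = NA_character_
  )
}
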