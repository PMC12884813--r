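test_that("levenshtein matches known distances and the DP oracle", {
  expect_equal(levenshtein("ACGT", "ACGT"), 0L)
  expect_equal(levenshtein("", "ACG"), 3L)
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  expect_equal(levenshtein("flaw", "lawn"), 2L)
  set.seed(42)
  s <- random_dna(200, 0, 15)
  t <- random_dna(200, 0, 15)
  expect_equal(levenshtein(s, t),
               mapply(oracle_levenshtein, s, t, USE.NAMES = FALSE))
  # metric properties
  expect_equal(levenshtein(s, t), levenshtein(t, s))
  u <- random_dna(200, 0, 15)
  expect_true(all(levenshtein(s, u) <= levenshtein(s, t) + levenshtein(t, u)))
})

test_that("bcr_similarity implements the normalized-distance formula exactly", {
  expect_equal(bcr_similarity("ACGTACGTAC", "ACGTACGTAC"), 1.0)
  expect_equal(bcr_similarity("ACGTACGTAC", "ACGTACGTAG"), 0.9)
  expect_equal(bcr_similarity("A", "GGGG"), 1 - 4 / 2.5)  # -0.6, unclamped
  expect_error(bcr_similarity("", "ACGT"), class = "repclone_parameter_error")
})

test_that("strict TCR keys separate cells by CDR3 nucleotide and by VDJC genes", {
  base <- make_tcell("BC1")
  same <- make_tcell("BC2")
  expect_equal(tcr_clonotype_key(base), tcr_clonotype_key(same))
  one_base <- make_tcell("BC3", b_cdr3_nt = "TGTGCC")
  expect_false(tcr_clonotype_key(one_base) == tcr_clonotype_key(base))
  diff_v <- make_tcell("BC4", b_v = "TRBV2")
  expect_false(tcr_clonotype_key(diff_v) == tcr_clonotype_key(base))
})

test_that("BCR clustering links through intermediates (single linkage)", {
  # A~B and B~C at 0.90, A~C at 0.80: transitive closure puts all in one clone
  A <- "AAAAAAAAAA"
  B <- "AAAAAAAAAC"
  C <- "AAAAAAAACC"
  expect_equal(bcr_similarity(A, B), 0.9)
  expect_equal(bcr_similarity(B, C), 0.9)
  expect_equal(bcr_similarity(A, C), 0.8)
  cells <- dplyr::bind_rows(
    make_bcell("BC1", A), make_bcell("BC2", B), make_bcell("BC3", C)
  )
  asg <- call_clonotypes(cells, method = "bcr_cluster", threshold = 0.85)
  expect_equal(dplyr::n_distinct(asg$clonotype_id), 1)

  # identical CDR3s but different heavy V genes stay apart
  cells2 <- dplyr::bind_rows(
    make_bcell("BC1", A, h_v = "IGHV-S01"), make_bcell("BC2", A, h_v = "IGHV-S02")
  )
  asg2 <- call_clonotypes(cells2, method = "bcr_cluster")
  expect_equal(dplyr::n_distinct(asg2$clonotype_id), 2)
})

test_that("clustering at threshold 1 degenerates to exact (V, CDR3) grouping", {
  set.seed(7)
  cdr3 <- sample(random_dna(8, 12, 18), 30, replace = TRUE)
  vg <- sample(c("IGHV-S01", "IGHV-S02"), 30, replace = TRUE)
  cells <- purrr::map(seq_len(30), function(i)
    make_bcell(paste0("BC", i), cdr3[i], h_v = vg[i])) |> purrr::list_rbind()
  asg <- call_clonotypes(cells, method = "bcr_cluster", threshold = 1)
  expect_equal(dplyr::n_distinct(asg$clonotype_id),
               dplyr::n_distinct(paste(vg, cdr3, cells$b_v_gene, cells$b_cdr3_nt)))
})

test_that("clustering equals the brute-force union-find oracle on random sets", {
  set.seed(99)
  for (trial in 1:40) {
    n <- sample(2:50, 1)
    cdr3 <- random_dna(n, 9, 15)
    vg <- sample(c("IGHV-S01", "IGHV-S02"), n, replace = TRUE)
    cells <- purrr::map(seq_len(n), function(i)
      make_bcell(paste0("BC", i), cdr3[i], h_v = vg[i],
                 l_cdr3 = "TGTCAACAA")) |> purrr::list_rbind()
    thr <- sample(c(0.7, 0.85, 0.95), 1)
    asg <- call_clonotypes(cells, method = "bcr_cluster", threshold = thr)
    asg <- asg[match(cells$barcode, asg$barcode), ]  # restore input order
    truth <- oracle_bcr_clusters(vg, cdr3, thr)
    expect_equal(oracle_ari(asg$clonotype_id, truth), 1)
  }
})

test_that("lowering the threshold never increases the number of clusters", {
  set.seed(5)
  cdr3 <- random_dna(40, 10, 16)
  cells <- purrr::map(seq_len(40), function(i)
    make_bcell(paste0("BC", i), cdr3[i])) |> purrr::list_rbind()
  ks <- vapply(c(0.95, 0.85, 0.7, 0.5, 0.3), function(thr) {
    dplyr::n_distinct(call_clonotypes(cells, method = "bcr_cluster",
                                      threshold = thr)$clonotype_id)
  }, numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("clonotype membership partitions the cells and frequencies sum to 1", {
  sim <- generate_tcr_repertoire(sim_config(seed = 31, n_cells = 300, n_clones = 60))
  pairs <- filter_paired_cells(sim$contigs, sim$barcodes, "T")
  asg <- call_clonotypes(pairs)
  expect_equal(nrow(asg), nrow(pairs))
  expect_false(any(is.na(asg$clonotype_id)))
  clones <- summarise_clonotypes(asg)
  per_sample <- dplyr::summarise(dplyr::group_by(clones, sample_id),
                                 total = sum(freq), n = sum(size))
  expect_equal(per_sample$total, rep(1, nrow(per_sample)), tolerance = 1e-9)
  expect_equal(sum(clones$size), nrow(pairs))
})

test_that("invalid thresholds are rejected", {
  cells <- make_bcell("BC1", "ACGTACGTACGT")
  expect_error(call_clonotypes(cells, method = "bcr_cluster", threshold = 0),
               class = "repclone_parameter_error")
  expect_error(call_clonotypes(cells, method = "bcr_cluster", threshold = 1.2),
               class = "repclone_parameter_error")
})
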