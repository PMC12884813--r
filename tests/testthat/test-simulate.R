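test_that("generators are deterministic under a fixed seed, down to the bytes", {
  cfg <- sim_config(seed = 71, n_cells = 120, n_clones = 30,
                    pathogen_spikes = c(EBV = 0.05))
  a <- generate_tcr_repertoire(cfg)
  b <- generate_tcr_repertoire(cfg)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$truth_cells, b$truth_cells)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_repertoire(a, d1); f2 <- write_repertoire(b, d2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  bcfg <- sim_config(seed = 72, n_cells = 80, n_clones = 15)
  expect_identical(generate_bcr_repertoire(bcfg)$contigs,
                   generate_bcr_repertoire(bcfg)$contigs)
  expect_identical(generate_isoform_reads(seed = 3)$reads,
                   generate_isoform_reads(seed = 3)$reads)
})

test_that("distinct strict keys after QC never exceed the clone budget", {
  sim <- generate_tcr_repertoire(sim_config(seed = 73, n_cells = 1000, n_clones = 500))
  pairs <- filter_paired_cells(sim$contigs, sim$barcodes, "T")
  asg <- call_clonotypes(pairs)
  expect_lte(dplyr::n_distinct(asg$clonotype_key), 500)
})

test_that("the QC truth record matches the generated artifacts", {
  cfg <- sim_config(seed = 74, n_cells = 300, n_clones = 50,
                    dropout_rate = 0.1, multichain_rate = 0.1,
                    gex_dropout_rate = 0.05)
  for (sim in list(generate_tcr_repertoire(cfg),
                   generate_bcr_repertoire(cfg))) {
    cls <- if (any(sim$contigs$locus == "IGH")) "B" else "T"
    pairs <- filter_paired_cells(sim$contigs, sim$barcodes, cls)
    expect_setequal(pairs$barcode, sim$truth_cells$barcode[sim$truth_cells$qc_expected])
    # multichain cells survive QC (resolution picks the dominant chain)
    multi <- sim$truth_cells$barcode[sim$truth_cells$multichain &
                                       sim$truth_cells$qc_expected]
    expect_true(all(multi %in% pairs$barcode))
  }
})

test_that("uniform clone-size law matches the closed-form Shannon entropy", {
  # equal clone weights with cells distributed evenly: build directly from truth
  sim <- generate_tcr_repertoire(sim_config(seed = 75, n_cells = 600, n_clones = 40,
                                            clone_size_law = "uniform",
                                            dropout_rate = 0, multichain_rate = 0,
                                            gex_dropout_rate = 0))
  pairs <- filter_paired_cells(sim$contigs, sim$barcodes, "T")
  asg <- call_clonotypes(pairs)
  clones <- summarise_clonotypes(asg)
  # the pipeline must reproduce the truth-record composition exactly
  truth_sizes <- sort(sim$truth_clones$size)
  expect_equal(sort(clones$size), truth_sizes)
  expect_equal(truth_sizes, rep(15L, 40))  # even allocation: 600 / 40
  expect_equal(repertoire_summary(asg)$shannon, log(40), tolerance = 1e-9)
})

test_that("group scenarios scale diversity in the intended direction", {
  cfg <- sim_config(seed = 76, n_cells = 400, n_clones = 80,
                    group_scenarios = scenario_two_group(n_samples = 2))
  sim <- generate_tcr_repertoire(cfg)
  summ <- repertoire_summary(
    call_clonotypes(filter_paired_cells(sim$contigs, sim$barcodes, "T")))
  med <- tapply(summ$shannon, summ$group, median)
  expect_gt(med[["HD"]], med[["CAR"]])
})

test_that("infeasible spike configurations are rejected", {
  expect_error(sim_config(seed = 1, pathogen_spikes = c(EBV = 0.8, CMV = 0.4)),
               class = "repclone_parameter_error")
  expect_error(sim_config(seed = 1, n_cells = 100, n_clones = 200),
               class = "repclone_parameter_error")
  cfg <- sim_config(seed = 1, n_cells = 50, n_clones = 10,
                    pathogen_spikes = c(NOSUCH = 0.5))
  expect_error(generate_tcr_repertoire(cfg), "NOSUCH",
               class = "repclone_parameter_error")
})

test_that("BCR construction keeps clones recoverable at the default threshold", {
  sim <- generate_bcr_repertoire(sim_config(seed = 77, n_cells = 250, n_clones = 35))
  pairs <- filter_paired_cells(sim$contigs, sim$barcodes, "B")
  asg <- call_clonotypes(pairs, method = "bcr_cluster", threshold = 0.85)
  truth <- dplyr::filter(sim$truth_cells, qc_expected)
  j <- dplyr::inner_join(asg, dplyr::select(truth, barcode, clone_id),
                         by = "barcode")
  expect_equal(oracle_ari(j$clonotype_id, j$clone_id), 1)
})
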