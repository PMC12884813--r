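db_fixture <- function() {
  tibble::tibble(
    cdr3_aa = c("CASSEBVF", "CAVCMVAF", "CASSCMVF", "CASSEBVF", "CASSMUSF"),
    chain = c("beta", "alpha", "beta", "beta", "beta"),
    v_gene = c("", "", "TRBV7", "", ""),
    j_gene = "",
    epitope = c("GLC", "NLV", "IPS", "RAK", "MMM"),
    pathogen = c("EBV", "CMV", "CMV", "HSV", "EBV"),
    species = c("HomoSapiens", "HomoSapiens", "HomoSapiens", "HomoSapiens",
                "MusMusculus")
  )
}

test_that("single-chain CDR3 matches annotate cells with their pathogens", {
  cells <- dplyr::bind_rows(
    make_tcell("BC1", b_cdr3_aa = "CASSEBVF"),             # beta match: EBV+HSV
    make_tcell("BC2", a_cdr3_aa = "CAVCMVAF"),             # alpha match: CMV
    make_tcell("BC3", a_cdr3_aa = "CAVCMVAF", b_cdr3_aa = "CASSEBVF"),
    make_tcell("BC4")                                      # no match
  )
  ann <- annotate_cells(cells, db_fixture())
  expect_equal(ann$matched_chain, c("beta", "alpha", "both", "none"))
  expect_equal(ann$pathogens[[1]], c("EBV", "HSV"))
  expect_equal(ann$pathogens[[2]], "CMV")
  expect_equal(sort(ann$pathogens[[3]]), c("CMV", "EBV", "HSV"))
  expect_equal(ann$pathogens[[4]], character(0))
})

test_that("matching is case-insensitive, species-restricted and V-gene aware", {
  cells <- make_tcell("BC1", b_cdr3_aa = "cassebvf")
  ann <- annotate_cells(cells, db_fixture())
  expect_true("EBV" %in% ann$pathogens[[1]])

  # the MusMusculus EBV entry must not fire under the default species
  cells2 <- make_tcell("BC1", b_cdr3_aa = "CASSMUSF")
  ann2 <- annotate_cells(cells2, db_fixture())
  expect_equal(ann2$matched_chain, "none")
  ann2b <- annotate_cells(cells2, db_fixture(), species = "MusMusculus")
  expect_equal(ann2b$pathogens[[1]], "EBV")

  # v-gene requirement: entry CASSCMVF needs TRBV7
  cells3 <- make_tcell("BC1", b_cdr3_aa = "CASSCMVF", b_v = "TRBV1")
  expect_true("CMV" %in%
    annotate_cells(cells3, db_fixture())$pathogens[[1]])
  expect_equal(
    annotate_cells(cells3, db_fixture(), require_v_gene = TRUE)$matched_chain,
    "none")
  cells4 <- make_tcell("BC1", b_cdr3_aa = "CASSCMVF", b_v = "TRBV7")
  expect_true("CMV" %in%
    annotate_cells(cells4, db_fixture(), require_v_gene = TRUE)$pathogens[[1]])
})

test_that("Hamming-1 matching is available behind a flag and off by default", {
  cells <- make_tcell("BC1", b_cdr3_aa = "CASSEBVW")  # 1 mismatch to CASSEBVF
  expect_equal(annotate_cells(cells, db_fixture())$matched_chain, "none")
  ann <- annotate_cells(cells, db_fixture(), max_mismatch = 1)
  expect_true("EBV" %in% ann$pathogens[[1]])
})

test_that("pathogen percentages and subset diversity follow their definitions", {
  cells <- purrr::map(1:100, function(i) {
    make_tcell(sprintf("BC%03d", i),
               a_cdr3_nt = paste0(rep("TGT", 4), collapse = ""),
               b_cdr3_nt = sprintf("TGTGC%s", paste(
                 rep(c("A", "C", "G", "T"), 5)[1:((i %% 5) * 3 + 3)], collapse = "")),
               b_cdr3_aa = if (i <= 10) "CASSEBVF" else sprintf("CXX%02dF", i))
  }) |> purrr::list_rbind()
  # make the 10 matched cells 5 distinct clonotypes of 2 cells each
  cells$b_cdr3_nt[1:10] <- rep(sprintf("TGTGCAAA%s", c("A", "C", "G", "T", "AA")),
                               each = 2)
  cells$b_cdr3_nt[11:100] <- sprintf("TGTGCACA%02d", 11:100)
  asg <- call_clonotypes(cells, method = "tcr_strict")
  ann <- annotate_cells(cells, db_fixture())
  pm <- pathogen_metrics(ann, asg)
  ebv <- dplyr::filter(pm, pathogen == "EBV")
  expect_equal(ebv$n_matched, 10L)
  expect_equal(ebv$pct, 10.0)
  expect_equal(ebv$diversity, log(5), tolerance = 1e-9)
})

test_that("empty subsets report zero percentage and missing diversity", {
  cells <- dplyr::bind_rows(make_tcell("BC1"), make_tcell("BC2"))
  asg <- call_clonotypes(cells, method = "tcr_strict")
  ann <- annotate_cells(cells, db_fixture())
  expect_error(pathogen_metrics(ann, asg, pathogens = "EBV"),
               class = "repclone_parameter_error")  # nothing matched: unknown label
  cells2 <- dplyr::bind_rows(make_tcell("BC1", b_cdr3_aa = "CASSEBVF"),
                             make_tcell("BC2"))
  asg2 <- call_clonotypes(cells2, method = "tcr_strict")
  ann2 <- annotate_cells(cells2, db_fixture())
  pm2 <- pathogen_metrics(ann2, asg2, pathogens = "EBV")
  expect_equal(pm2$pct, 50)
  expect_error(pathogen_metrics(ann2, asg2, pathogens = "NOSUCH"), "EBV",
               class = "repclone_parameter_error")
})

test_that("removing annotated cells and re-annotating yields zero matches", {
  sim <- generate_tcr_repertoire(sim_config(seed = 51, n_cells = 400, n_clones = 60,
                                            pathogen_spikes = c(EBV = 0.08)))
  pairs <- filter_paired_cells(sim$contigs, sim$barcodes, "T")
  ann <- annotate_cells(pairs, sim$pathogen_db)
  hit <- ann$barcode[ann$matched_chain != "none"]
  expect_gt(length(hit), 0)
  rest <- dplyr::filter(pairs, !barcode %in% hit)
  ann2 <- annotate_cells(rest, sim$pathogen_db)
  expect_true(all(ann2$matched_chain == "none"))
})

test_that("spiked clones are recovered by annotation (constructed match)", {
  sim <- generate_tcr_repertoire(sim_config(seed = 52, n_cells = 500, n_clones = 50,
                                            pathogen_spikes = c(CMV = 0.1)))
  pairs <- filter_paired_cells(sim$contigs, sim$barcodes, "T")
  ann <- annotate_cells(pairs, sim$pathogen_db)
  truth <- dplyr::filter(sim$truth_cells, qc_expected)
  spiked <- truth$barcode[!is.na(truth$pathogen)]
  got <- ann$barcode[purrr::map_lgl(ann$pathogens, ~ "CMV" %in% .x)]
  expect_true(all(spiked %in% got))
})
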