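two_group_df <- function(x, y) {
  data.frame(group = rep(c("A", "B"), c(length(x), length(y))),
             value = c(x, y))
}

test_that("Mann-Whitney: exact enumeration for small untied groups", {
  cmp <- compare_groups(two_group_df(c(1, 2, 3), c(10, 11, 12)),
                        test = "mann_whitney")
  expect_true(cmp$exact)
  expect_equal(cmp$p_value, 0.1)
  expect_equal(cmp$p_value, oracle_mw_exact_p(c(1, 2, 3), c(10, 11, 12)))
})

test_that("Mann-Whitney: identical value multisets give a null-centered test", {
  cmp <- compare_groups(two_group_df(c(1, 2, 3, 4), c(1, 2, 3, 4)),
                        test = "mann_whitney")
  expect_gt(cmp$p_value, 0.9)
})

test_that("exact Mann-Whitney agrees with the enumeration oracle on random data", {
  set.seed(13)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(stats::rnorm(n1), 6)
    y <- round(stats::rnorm(n2, sample(c(0, 1), 1)), 6)
    cmp <- compare_groups(two_group_df(x, y), test = "mann_whitney")
    expect_equal(cmp$p_value, oracle_mw_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("large or tied samples fall back to the tie-corrected normal approximation", {
  set.seed(14)
  x <- stats::rnorm(20); y <- stats::rnorm(20)
  cmp <- compare_groups(two_group_df(x, y), test = "mann_whitney")
  expect_false(cmp$exact)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(cmp$p_value, ref$p.value)
  # ties force the approximation even at small n
  cmp2 <- compare_groups(two_group_df(c(1, 1, 2), c(2, 3, 3)),
                         test = "mann_whitney")
  expect_false(cmp2$exact)
  expect_true(is.finite(cmp2$p_value))
})

test_that("Kruskal-Wallis + Dunn behaves on degenerate and separated groups", {
  d <- data.frame(group = rep(c("A", "B", "C"), each = 4),
                  value = rep(c(1, 2, 3, 4), 3))
  cmp <- compare_groups(d, test = "kruskal_wallis_dunn")
  expect_lt(cmp$statistic, 1e-9)
  expect_gt(cmp$p_value, 0.99)
  # Dunn adjusted p-values never drop below the raw ones
  d2 <- data.frame(group = rep(c("A", "B", "C"), each = 5),
                   value = c(stats::rnorm(5), stats::rnorm(5, 3), stats::rnorm(5, 6)))
  cmp2 <- compare_groups(d2, test = "kruskal_wallis_dunn")
  pw <- tidy(cmp2)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adjusted >= pw$p_value - 1e-12))
  expect_true(all(pw$p_adjusted <= 1))
  # the overall statistic is kruskal.test's
  expect_equal(cmp2$statistic,
               unname(stats::kruskal.test(value ~ group, d2)$statistic))
})

test_that("wrong group counts raise parameter errors", {
  d <- data.frame(group = rep(c("A", "B", "C"), each = 3), value = rnorm(9))
  expect_error(compare_groups(d, test = "mann_whitney"),
               class = "repclone_parameter_error")
  d2 <- data.frame(group = rep(c("A", "B"), each = 3), value = rnorm(6))
  expect_error(compare_groups(d2, test = "kruskal_wallis_dunn"),
               class = "repclone_parameter_error")
})

test_that("tidy() and glance() expose broom-shaped results", {
  d <- two_group_df(1:4, 5:8)
  cmp <- compare_groups(d, test = "mann_whitney")
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("group1", "group2", "statistic", "p_value", "p_adjusted"))
  gl <- glance(cmp)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_total, 8)
  expect_match(gl$method, "Mann-Whitney")
})

test_that("the pipeline writes a manifest and is byte-stable on re-run", {
  tcr <- generate_tcr_repertoire(sim_config(seed = 81, n_cells = 150, n_clones = 30,
                                            group_scenarios = scenario_two_group(n_samples = 2),
                                            pathogen_spikes = c(EBV = 0.05)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_pipeline(tcr = tcr, out_dir = d1, seed = 81)
  r2 <- run_pipeline(tcr = tcr, out_dir = d2, seed = 81)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  m <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_true(all(c("tcr_summary", "tcr_pathogen_metrics") %in% names(m$stages)))
  tsv1 <- list.files(d1, pattern = "\\.tsv$", full.names = TRUE)
  tsv2 <- file.path(d2, basename(tsv1))
  expect_identical(unname(tools::md5sum(tsv1)), unname(tools::md5sum(tsv2)))
  # a run without BCR input simply has no BCR outputs, and still succeeds
  expect_false(any(grepl("^bcr", names(r1$files))))
})

test_that("plot helpers return ggplot objects", {
  sim <- generate_tcr_repertoire(sim_config(seed = 82, n_cells = 120, n_clones = 25,
                                            group_scenarios = scenario_two_group(n_samples = 2)))
  asg <- call_clonotypes(filter_paired_cells(sim$contigs, sim$barcodes, "T"))
  summ <- repertoire_summary(asg)
  expect_s3_class(plot_lorenz(lorenz_by_sample(asg)), "ggplot")
  expect_s3_class(plot_shannon(summ), "ggplot")
  expect_s3_class(plot_expansion_bins(summ), "ggplot")
  cmp <- compare_groups(dplyr::rename(summ, value = shannon), test = "mann_whitney")
  expect_s3_class(ggplot2::autoplot(cmp), "ggplot")
})
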