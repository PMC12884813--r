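#' Simulation configuration for synthetic repertoires
#'
#' Bundles and validates the knobs of the synthetic-repertoire generator:
#' clone-size law, group scenarios (diversity and expansion shifts between
#' sample groups), pathogen spike-in fractions, somatic-hypermutation rate,
#' and the technical artifact rates (chain dropout, extra chains, barcodes
#' missing from the transcriptome).
#'
#' @param seed Integer random seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @param n_cells Cells per sample (default 2000).
#' @param n_clones Target clone count per sample before group scaling
#'   (default 200).
#' @param clone_size_law `"powerlaw"` (weights `i^-shape`, default),
#'   `"geometric"` (weights `(1-shape)^(i-1)`, `shape` in (0,1)), or
#'   `"uniform"`.
#' @param shape Shape parameter of the clone-size law (power-law exponent
#'   1.5 by default).
#' @param group_scenarios Tibble with columns `group`, `n_samples`,
#'   `diversity_multiplier` (scales the clone count: lower = fewer clones =
#'   lower diversity) and `expansion_boost` (multiplies `shape`: higher =
#'   more skewed clone sizes). Default: a single healthy-donor-like group.
#' @param pathogen_spikes Named numeric vector of spike fractions, e.g.
#'   `c(EBV = 0.1)`: that fraction of cells receives a beta-chain CDR3 copied
#'   from a database entry of the pathogen. Fractions must sum to at most 1.
#' @param shm_rate Per-site substitution probability applied to germline V
#'   segments in BCR simulation (default 0.02).
#' @param multichain_rate Fraction of cells given a spurious extra chain with
#'   lower UMI support (default 0.05).
#' @param dropout_rate Fraction of cells missing one chain (default 0.05);
#'   these must fail QC.
#' @param gex_dropout_rate Fraction of cells absent from the transcriptome
#'   barcode table (default 0.03); these must fail QC.
#' @return A validated `sim_config` object (list).
#' @export
sim_config <- function(seed = 1L, n_cells = 2000L, n_clones = 200L,
                       clone_size_law = c("powerlaw", "geometric", "uniform"),
                       shape = 1.5,
                       group_scenarios = NULL,
                       pathogen_spikes = NULL,
                       shm_rate = 0.02,
                       multichain_rate = 0.05,
                       dropout_rate = 0.05,
                       gex_dropout_rate = 0.03) {
  clone_size_law <- match.arg(clone_size_law)
  if (is.null(group_scenarios)) {
    group_scenarios <- tibble(group = "HD", n_samples = 1L,
                              diversity_multiplier = 1, expansion_boost = 1)
  }
  rates <- c(shm_rate = shm_rate, multichain_rate = multichain_rate,
             dropout_rate = dropout_rate, gex_dropout_rate = gex_dropout_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("all rates must lie in [0, 1]", class = "repclone_parameter_error")
  }
  if (!is.null(pathogen_spikes)) {
    if (is.null(names(pathogen_spikes)) || any(!nzchar(names(pathogen_spikes)))) {
      abort("pathogen_spikes must be a named vector", class = "repclone_parameter_error")
    }
    if (any(pathogen_spikes < 0) || sum(pathogen_spikes) > 1) {
      abort("pathogen spike fractions must be non-negative and sum to <= 1",
            class = "repclone_parameter_error")
    }
  }
  if (n_clones > n_cells) {
    abort("n_clones must not exceed n_cells", class = "repclone_parameter_error")
  }
  if (clone_size_law == "geometric" && (shape <= 0 || shape >= 1)) {
    abort("geometric clone-size law needs shape in (0, 1)",
          class = "repclone_parameter_error")
  }
  structure(list(
    seed = as.integer(seed), n_cells = as.integer(n_cells),
    n_clones = as.integer(n_clones), clone_size_law = clone_size_law,
    shape = shape, group_scenarios = as_tibble(group_scenarios),
    pathogen_spikes = pathogen_spikes, shm_rate = shm_rate,
    multichain_rate = multichain_rate, dropout_rate = dropout_rate,
    gex_dropout_rate = gex_dropout_rate
  ), class = "sim_config")
}

#' Two-group scenario with reduced post-treatment diversity
#'
#' Convenience scenario emulating the contrast between healthy-donor-like
#' repertoires and post-CAR-T-like repertoires with contracted diversity and
#' boosted clonal expansion.
#'
#' @param n_samples Samples per group (default 3).
#' @param multiplier Diversity multiplier of the treated group (default 0.3).
#' @param boost Expansion boost of the treated group (default 2).
#' @return Tibble usable as `group_scenarios` in [sim_config()].
#' @export
scenario_two_group <- function(n_samples = 3L, multiplier = 0.3, boost = 2) {
  tibble(group = c("HD", "CAR"), n_samples = as.integer(n_samples),
         diversity_multiplier = c(1, multiplier), expansion_boost = c(1, boost))
}

#' Generate a synthetic paired-chain TCR repertoire
#'
#' Builds contig and barcode tables with known ground truth: clone sizes are
#' drawn from the configured law; each clone carries random in-frame TRA/TRB
#' CDR3 nucleotide sequences (24-60 nt) and gene calls from fixture pools;
#' pathogen spike-ins copy beta-chain CDR3 amino-acid sequences from the
#' reference database (back-translated with a fixed codon table) so that
#' exact amino-acid matching recovers them; chain-dropout, extra-chain and
#' transcriptome-dropout artifacts are injected at the configured rates and
#' recorded in the truth tables.
#'
#' @param config A [sim_config()] object.
#' @param pathogen_db Reference database tibble (default the bundled
#'   synthetic database).
#' @return A list of class `tcr_sim`: `contigs`, `barcodes`, `pathogen_db`,
#'   `truth_cells` (with `qc_expected`, the cells that must survive QC),
#'   `truth_clones`, `config`.
#' @export
generate_tcr_repertoire <- function(config, pathogen_db = repclone_pathogen_db()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    samples <- expand_samples(config)
    parts <- purrr::pmap(samples, function(sample_id, group, diversity_multiplier,
                                           expansion_boost) {
      simulate_tcr_sample(config, sample_id, group, diversity_multiplier,
                          expansion_boost, pathogen_db)
    })
    assemble_sim(parts, config, pathogen_db = pathogen_db, class = "tcr_sim")
  })
}

#' Generate a synthetic paired-chain BCR repertoire
#'
#' Like [generate_tcr_repertoire()] but for B cells: every clone gets a
#' heavy-chain germline V gene and a founder CDR3 whose similarity to any
#' other same-V founder is rejection-sampled below 0.7, and clone members
#' carry CDR3 variants within `floor(0.075 * L)` substitutions of the
#' founder, so the true partition is exactly recoverable by 0.85-similarity
#' clustering. Observed heavy-chain V sequences are germline sequences with
#' independent per-site substitutions at `shm_rate`, and the injected
#' mutation count per cell is recorded in the truth table.
#'
#' @param config A [sim_config()] object.
#' @param germline Germline reference tibble (default the bundled synthetic
#'   FASTA).
#' @return A list of class `bcr_sim`: `contigs`, `barcodes`, `germline`,
#'   `truth_cells`, `truth_clones`, `config`.
#' @export
generate_bcr_repertoire <- function(config, germline = repclone_germline()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    samples <- expand_samples(config)
    parts <- purrr::pmap(samples, function(sample_id, group, diversity_multiplier,
                                           expansion_boost) {
      simulate_bcr_sample(config, sample_id, group, diversity_multiplier,
                          expansion_boost, germline)
    })
    assemble_sim(parts, config, germline = germline, class = "bcr_sim")
  })
}

#' Generate a synthetic CD45 isoform read table
#'
#' Each read is an RA-type read with probability `ra_fraction` — its isoform
#' drawn uniformly from the exon-4-containing isoforms (RAX, RABX, RABCX) —
#' and an RX (CD45RO) read otherwise. Exon evidence is emitted fully
#' consistent with the drawn isoform, so the per-read probability vector is
#' concentrated on the truth.
#'
#' @param n_barcodes,reads_per_barcode Table dimensions.
#' @param ra_fraction Probability a read comes from an RA-type isoform.
#' @param seed Random seed.
#' @return List with `reads` (tibble `barcode`, `read_id`, `exons_present`,
#'   `exons_absent`, `isoform`) and `truth` (per-barcode RA read counts).
#' @export
generate_isoform_reads <- function(n_barcodes = 100, reads_per_barcode = 50,
                                   ra_fraction = 0.5, seed = 1L) {
  if (ra_fraction < 0 || ra_fraction > 1) {
    abort("ra_fraction must lie in [0, 1]", class = "repclone_parameter_error")
  }
  withr::with_seed(seed, {
    bc <- sprintf("CELL%04d", seq_len(n_barcodes))
    reads <- tidyr::expand_grid(barcode = bc, idx = seq_len(reads_per_barcode)) |>
      mutate(read_id = sprintf("%s_R%04d", .data$barcode, .data$idx)) |>
      select(-"idx")
    n <- nrow(reads)
    is_ra <- runif(n) < ra_fraction
    iso <- ifelse(is_ra, sample(c("RAX", "RABX", "RABCX"), n, replace = TRUE), "RX")
    pres <- vapply(iso, function(i) paste(cd45_isoform_exons[[i]], collapse = ","),
                   character(1), USE.NAMES = FALSE)
    absent <- vapply(iso, function(i)
      paste(setdiff(4:6, cd45_isoform_exons[[i]]), collapse = ","),
      character(1), USE.NAMES = FALSE)
    reads <- mutate(reads, exons_present = pres, exons_absent = absent, isoform = iso)
    truth <- reads |>
      group_by(.data$barcode) |>
      summarise(n_reads = n(), n_ra = sum(.data$isoform != "RX"),
                true_ra_fraction = ra_fraction, .groups = "drop")
    list(reads = reads, truth = truth)
  })
}

#' Write a simulated repertoire to disk
#'
#' Serializes a simulation into the same plain-text formats the readers
#' consume: the contig table (chosen dialect), the transcriptome barcode
#' table, the pathogen database or germline FASTA, and the truth tables.
#'
#' @param sim Output of [generate_tcr_repertoire()] or
#'   [generate_bcr_repertoire()].
#' @param dir Output directory (created if needed).
#' @param dialect Contig dialect to write.
#' @return Named character vector of the files written, invisibly.
#' @export
write_repertoire <- function(sim, dir, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (dialect == "tenx_csv") "csv" else "tsv"
  files <- c(contigs = file.path(dir, paste0("contigs.", ext)),
             barcodes = file.path(dir, "barcodes.tsv"),
             truth_cells = file.path(dir, "truth_cells.tsv"),
             truth_clones = file.path(dir, "truth_clones.tsv"))
  write_contigs(sim$contigs, files[["contigs"]], dialect)
  readr::write_tsv(sim$barcodes, files[["barcodes"]], progress = FALSE)
  readr::write_tsv(sim$truth_cells, files[["truth_cells"]], progress = FALSE)
  readr::write_tsv(sim$truth_clones, files[["truth_clones"]], progress = FALSE)
  if (!is.null(sim$pathogen_db)) {
    files[["pathogen_db"]] <- file.path(dir, "pathogen_db.tsv")
    readr::write_tsv(sim$pathogen_db, files[["pathogen_db"]], progress = FALSE)
  }
  if (!is.null(sim$germline)) {
    files[["germline"]] <- file.path(dir, "germline.fasta")
    write_germline_fasta(sim$germline, files[["germline"]])
  }
  invisible(files)
}

# ---- internal ----------------------------------------------------------------

expand_samples <- function(config) {
  purrr::pmap(config$group_scenarios,
              function(group, n_samples, diversity_multiplier, expansion_boost, ...) {
    tibble(sample_id = sprintf("%s_S%d", group, seq_len(n_samples)),
           group = group,
           diversity_multiplier = diversity_multiplier,
           expansion_boost = expansion_boost)
  }) |> list_rbind()
}

clone_weights <- function(k, law, shape, boost) {
  i <- seq_len(k)
  w <- switch(law,
    uniform = rep(1, k),
    geometric = (1 - min(shape * boost, 0.99))^(i - 1),
    powerlaw = i^(-shape * boost)
  )
  w / sum(w)
}

random_cdr3_nt <- function(n) {
  vapply(seq_len(n), function(i) {
    n_codons <- sample(8:20, 1)  # 24-60 nt, multiple of 3
    paste(sample(sense_codons, n_codons, replace = TRUE), collapse = "")
  }, character(1))
}

translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt)))
}

# inject technical artifacts and package one sample's cells into contig rows
build_sample_tables <- function(cells, config, sample_id, group, extra_chain_fun) {
  n <- nrow(cells)
  n_drop <- round(config$dropout_rate * n)
  n_multi <- round(config$multichain_rate * n)
  n_gex_drop <- round(config$gex_dropout_rate * n)
  shuffled <- sample(n)
  drop_idx <- shuffled[seq_len(n_drop)]
  multi_idx <- shuffled[n_drop + seq_len(n_multi)]
  gex_drop_idx <- sample(n, n_gex_drop)

  cells <- cells |>
    mutate(dropout = row_number() %in% drop_idx,
           multichain = row_number() %in% multi_idx,
           in_gex = !(row_number() %in% gex_drop_idx),
           qc_expected = !.data$dropout & .data$in_gex)

  contig_rows <- function(prefix) {
    tibble(
      barcode = cells$barcode, sample_id = sample_id,
      locus = cells[[paste0(prefix, "locus")]],
      cdr3_nt = cells[[paste0(prefix, "cdr3_nt")]],
      cdr3_aa = cells[[paste0(prefix, "cdr3_aa")]],
      v_gene = cells[[paste0(prefix, "v_gene")]],
      d_gene = cells[[paste0(prefix, "d_gene")]],
      j_gene = cells[[paste0(prefix, "j_gene")]],
      c_gene = cells[[paste0(prefix, "c_gene")]],
      umi_count = cells[[paste0(prefix, "umi")]],
      read_count = cells[[paste0(prefix, "reads")]],
      productive = TRUE,
      sequence = cells[[paste0(prefix, "sequence")]]
    )
  }
  contigs <- bind_rows(contig_rows("a_"), contig_rows("b_"))

  # chain dropout: remove one randomly chosen chain of the cell
  if (length(drop_idx) > 0) {
    drop_locus <- ifelse(runif(length(drop_idx)) < 0.5,
                         cells$a_locus[drop_idx], cells$b_locus[drop_idx])
    drop_key <- paste(cells$barcode[drop_idx], drop_locus)
    contigs <- filter(contigs, !paste(.data$barcode, .data$locus) %in% drop_key)
  }
  # extra chains with strictly lower UMI than the kept chain
  if (length(multi_idx) > 0) {
    contigs <- bind_rows(contigs, extra_chain_fun(cells[multi_idx, ], sample_id))
  }
  contigs <- arrange(contigs, .data$barcode, .data$locus, desc(.data$umi_count))

  barcodes <- cells |>
    filter(.data$in_gex) |>
    transmute(barcode = .data$barcode, sample_id = sample_id, group = group)

  truth_cells <- cells |>
    transmute(barcode = .data$barcode, sample_id = sample_id, group = group,
              clone_id = .data$clone_id,
              pathogen = if ("pathogen" %in% names(cells)) .data$pathogen else NA_character_,
              n_mutations = if ("n_mutations" %in% names(cells)) .data$n_mutations else NA_integer_,
              dropout = .data$dropout, multichain = .data$multichain,
              in_gex = .data$in_gex, qc_expected = .data$qc_expected)
  truth_clones <- cells |>
    count(clone_id = .data$clone_id, name = "size") |>
    mutate(sample_id = sample_id, group = group) |>
    left_join(distinct(truth_cells, .data$clone_id, .data$pathogen), by = "clone_id") |>
    select("sample_id", "group", "clone_id", "size", "pathogen")

  list(contigs = contigs, barcodes = barcodes,
       truth_cells = truth_cells, truth_clones = truth_clones)
}

simulate_tcr_sample <- function(config, sample_id, group, multiplier, boost,
                                pathogen_db) {
  n_cells <- config$n_cells
  k <- max(1L, round(config$n_clones * multiplier))
  spikes <- config$pathogen_spikes %||% numeric(0)
  n_spike <- round(spikes * n_cells)
  n_norm <- n_cells - sum(n_spike)
  if (n_norm < 0) {
    abort("pathogen spikes exceed the cell budget", class = "repclone_parameter_error")
  }

  # ordinary clones; the uniform law allocates cells evenly and
  # deterministically so its diversity has a closed form (ln k)
  clone_of <- if (config$clone_size_law == "uniform") {
    rep_len(seq_len(k), n_norm)
  } else {
    w <- clone_weights(k, config$clone_size_law, config$shape, boost)
    sample.int(k, n_norm, replace = TRUE, prob = w)
  }
  clones <- tibble(
    clone_idx = seq_len(k),
    clone_id = sprintf("%s-CL%04d", sample_id, seq_len(k)),
    pathogen = NA_character_,
    a_cdr3_nt = random_cdr3_nt(k),
    b_cdr3_nt = random_cdr3_nt(k),
    a_v = sample(trav_genes, k, TRUE), a_j = sample(traj_genes, k, TRUE),
    b_v = sample(trbv_genes, k, TRUE), b_d = sample(trbd_genes, k, TRUE),
    b_j = sample(trbj_genes, k, TRUE), b_c = sample(trbc_genes, k, TRUE)
  )
  cell_clone <- clones$clone_idx[clone_of]

  # spiked clones copy a beta CDR3 (amino-acid level) from the database
  spike_cells <- purrr::imap(n_spike, function(n_p, p) {
    if (n_p == 0) return(NULL)
    entries <- filter(pathogen_db, .data$pathogen == p, .data$chain == "beta",
                      .data$species == "HomoSapiens")
    if (nrow(entries) == 0) {
      abort(sprintf("no beta-chain HomoSapiens entries for pathogen %s", p),
            class = "repclone_parameter_error")
    }
    m <- max(1L, min(nrow(entries), round(n_p / 10)))
    picked <- entries[sample.int(nrow(entries), m), ]
    sp <- tibble(
      clone_id = sprintf("%s-SPK-%s-%02d", sample_id, gsub("[^A-Za-z0-9]", "", p),
                         seq_len(m)),
      pathogen = p,
      a_cdr3_nt = random_cdr3_nt(m),
      b_cdr3_nt = backtranslate(picked$cdr3_aa),
      a_v = sample(trav_genes, m, TRUE), a_j = sample(traj_genes, m, TRUE),
      b_v = ifelse(nzchar(picked$v_gene), picked$v_gene, sample(trbv_genes, m, TRUE)),
      b_d = sample(trbd_genes, m, TRUE),
      b_j = sample(trbj_genes, m, TRUE), b_c = sample(trbc_genes, m, TRUE)
    )
    sp[sample.int(m, n_p, replace = TRUE), ]
  }) |> purrr::compact() |> bind_rows()

  base <- clones[cell_clone, ] |> select(-"clone_idx")
  cells <- bind_rows(base, spike_cells)
  n <- nrow(cells)
  cells <- cells[sample.int(n), ]  # shuffle so artifacts hit clones uniformly
  umi_a <- rpois(n, 2) + 2L
  umi_b <- rpois(n, 3) + 2L
  cells <- cells |>
    mutate(
      barcode = sprintf("%s-BC%05d", sample_id, seq_len(n)),
      a_locus = "TRA", b_locus = "TRB",
      a_cdr3_aa = translate_nt(.data$a_cdr3_nt),
      b_cdr3_aa = translate_nt(.data$b_cdr3_nt),
      a_v_gene = .data$a_v, a_d_gene = "", a_j_gene = .data$a_j, a_c_gene = "TRAC",
      b_v_gene = .data$b_v, b_d_gene = .data$b_d, b_j_gene = .data$b_j,
      b_c_gene = .data$b_c,
      a_umi = umi_a, b_umi = umi_b,
      a_reads = umi_a * sample(20:60, n, TRUE),
      b_reads = umi_b * sample(20:60, n, TRUE),
      a_sequence = NA_character_, b_sequence = NA_character_
    )

  extra_chain_fun <- function(mc, sid) {
    m <- nrow(mc)
    tibble(
      barcode = mc$barcode, sample_id = sid, locus = "TRB",
      cdr3_nt = random_cdr3_nt(m), cdr3_aa = NA_character_,
      v_gene = sample(trbv_genes, m, TRUE), d_gene = sample(trbd_genes, m, TRUE),
      j_gene = sample(trbj_genes, m, TRUE), c_gene = sample(trbc_genes, m, TRUE),
      umi_count = pmax(mc$b_umi - 1L, 1L), read_count = pmax(mc$b_reads %/% 2L, 1L),
      productive = TRUE, sequence = NA_character_
    ) |>
      mutate(cdr3_aa = translate_nt(.data$cdr3_nt))
  }
  build_sample_tables(cells, config, sample_id, group, extra_chain_fun)
}

simulate_bcr_sample <- function(config, sample_id, group, multiplier, boost,
                                germline) {
  n_cells <- config$n_cells
  k <- max(1L, round(config$n_clones * multiplier))
  heavy_ref <- filter(germline, str_detect(.data$gene_name, "^IGHV"))
  light_ref <- filter(germline, str_detect(.data$gene_name, "^IG[KL]V"))

  # founder CDR3s rejection-sampled below 0.7 similarity within each V gene
  founders <- character(k)
  h_v <- sample(heavy_ref$gene_name, k, TRUE)
  for (i in seq_len(k)) {
    repeat {
      cand <- random_cdr3_nt(1)
      same_v <- founders[seq_len(i - 1)][h_v[seq_len(i - 1)] == h_v[i]]
      if (length(same_v) == 0 || all(bcr_similarity(cand, same_v) < 0.7)) {
        founders[i] <- cand
        break
      }
    }
  }
  l_locus <- sample(c("IGK", "IGL"), k, TRUE)
  l_v <- ifelse(l_locus == "IGK", sample(igkv_genes, k, TRUE),
                sample(iglv_genes, k, TRUE))
  l_j <- ifelse(l_locus == "IGK", sample(igkj_genes, k, TRUE),
                sample(iglj_genes, k, TRUE))
  clones <- tibble(
    clone_idx = seq_len(k),
    clone_id = sprintf("%s-CL%04d", sample_id, seq_len(k)),
    h_v = h_v, founder = founders,
    h_d = sample(ighd_genes, k, TRUE), h_j = sample(ighj_genes, k, TRUE),
    h_c = sample(ighc_genes, k, TRUE, prob = c(0.4, 0.1, 0.25, 0.1, 0.15)),
    l_locus = l_locus, l_v = l_v, l_j = l_j,
    l_c = ifelse(l_locus == "IGK", "IGKC", "IGLC1"),
    l_cdr3 = random_cdr3_nt(k)
  )

  clone_of <- if (config$clone_size_law == "uniform") {
    rep_len(seq_len(k), n_cells)
  } else {
    w <- clone_weights(k, config$clone_size_law, config$shape, boost)
    sample.int(k, n_cells, replace = TRUE, prob = w)
  }
  cells <- clones[clone_of, ]
  n <- nrow(cells)

  # within-clone CDR3 variants: <= floor(0.075 * L) substitutions from the
  # founder keeps every within-clone pair at similarity >= 0.85
  mutate_cdr3 <- function(seq) {
    L <- nchar(seq)
    d_max <- floor(0.075 * L)
    d <- if (d_max > 0) sample.int(d_max + 1L, 1L) - 1L else 0L
    if (d == 0) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    pos <- sample.int(L, d)
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    paste(chars, collapse = "")
  }
  a_cdr3 <- vapply(cells$founder, mutate_cdr3, character(1), USE.NAMES = FALSE)

  # observed heavy V = germline with independent per-site substitutions
  ref_seq <- setNames(heavy_ref$sequence, heavy_ref$gene_name)
  mut_res <- purrr::map(cells$h_v, function(g) {
    s <- ref_seq[[g]]
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(chars)) < config$shm_rate)
    # substitutions at the outermost germline positions are unobservable
    # under end-free alignment (clipping ties or beats the mismatch), so
    # mutations are restricted to internal sites
    L <- length(chars)
    hit <- hit[hit > 2L & hit < L - 1L]
    for (p in hit) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    list(seq = paste(chars, collapse = ""), n = length(hit))
  })

  umi_a <- rpois(n, 3) + 2L
  umi_b <- rpois(n, 3) + 2L
  cells <- cells |>
    mutate(
      barcode = sprintf("%s-BC%05d", sample_id, seq_len(n)),
      n_mutations = purrr::map_int(mut_res, ~ .x$n),
      a_locus = "IGH", b_locus = .data$l_locus,
      a_cdr3_nt = a_cdr3, b_cdr3_nt = .data$l_cdr3,
      a_cdr3_aa = translate_nt(a_cdr3), b_cdr3_aa = translate_nt(.data$l_cdr3),
      a_v_gene = .data$h_v, a_d_gene = .data$h_d, a_j_gene = .data$h_j,
      a_c_gene = .data$h_c,
      b_v_gene = .data$l_v, b_d_gene = "", b_j_gene = .data$l_j,
      b_c_gene = .data$l_c,
      a_umi = umi_a, b_umi = umi_b,
      a_reads = umi_a * sample(20:60, n, TRUE),
      b_reads = umi_b * sample(20:60, n, TRUE),
      a_sequence = purrr::map_chr(mut_res, ~ .x$seq),
      b_sequence = NA_character_
    ) |>
    select(-"clone_idx")
  cells <- cells[sample.int(n), ]
  cells$barcode <- sprintf("%s-BC%05d", sample_id, seq_len(n))

  extra_chain_fun <- function(mc, sid) {
    m <- nrow(mc)
    tibble(
      barcode = mc$barcode, sample_id = sid, locus = "IGK",
      cdr3_nt = random_cdr3_nt(m), cdr3_aa = NA_character_,
      v_gene = sample(igkv_genes, m, TRUE), d_gene = "",
      j_gene = sample(igkj_genes, m, TRUE), c_gene = "IGKC",
      umi_count = pmax(mc$b_umi - 1L, 1L), read_count = pmax(mc$b_reads %/% 2L, 1L),
      productive = TRUE, sequence = NA_character_
    ) |>
      mutate(cdr3_aa = translate_nt(.data$cdr3_nt))
  }
  build_sample_tables(cells, config, sample_id, group, extra_chain_fun)
}

assemble_sim <- function(parts, config, pathogen_db = NULL, germline = NULL,
                         class) {
  out <- list(
    contigs = list_rbind(purrr::map(parts, "contigs")),
    barcodes = list_rbind(purrr::map(parts, "barcodes")),
    truth_cells = list_rbind(purrr::map(parts, "truth_cells")),
    truth_clones = list_rbind(purrr::map(parts, "truth_clones")),
    pathogen_db = pathogen_db, germline = germline, config = config
  )
  structure(out, class = c(class, "sim_repertoire"))
}
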