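# repclone

Tidy single-cell immune-repertoire analysis: from paired-chain V(D)J contig
tables to clonotypes, diversity statistics, pathogen-associated TCR
annotation, somatic-hypermutation quantification and CD45RA/RO isoform
totals.

## Who it is for

Groups analysing 10x-style single-cell TCR/BCR sequencing alongside
transcriptome data — for example to ask whether a treatment contracted the
T-cell repertoire, whether virus-associated clones expanded, or how mutated
the B-cell compartment is — and who want every step of that analysis as a
tested, composable R function rather than a one-off script. All functions
take a data frame first and return tibbles, so stages chain with the pipe.

## What it computes

* **QC/pairing**: cells must have both chains (α+β, or heavy+light), the
  dominant chain per class is kept by UMI count (ties: read count, then
  CDR3), and only transcriptome-detected barcodes are retained.
* **Clonotypes** — strict for TCR: identical CDR3 nucleotide sequence and
  identical V/D/J/C gene calls on both chains. Similarity-clustered for
  BCR: chains sharing a V gene are linked when
  `1 − Levenshtein(s,t) / ((|s|+|t|)/2) ≥ 0.85`
  on CDR3 nucleotide sequences, and clones are the connected components
  (single linkage).
* **Diversity**: Shannon entropy `−Σ X ln X`; expansion bins Rare
  `(0, 1e−4]` through Hyperexpanded `(0.1, 1]` (upper-inclusive); Lorenz
  curves and the Gini index; unique-clonotype %; singleton/clonal tallies.
* **Pathogen-associated TCRs**: exact single-chain amino-acid CDR3 matches
  (CDR3α or CDR3β) against a VDJdb/McPAS-style reference table; per-sample
  percentages and annotated-subset diversity.
* **SHM**: end-free alignment of observed V regions to germline
  (match +1 / mismatch −1 / gap −2, terminal gaps free); frequency =
  100 · (substitutions + indel events) / aligned germline length.
* **CD45 isoforms**: per-read probabilities over RAX/RABX/RBX/RBCX/RABCX/RX
  from exon 4–7 evidence; per-barcode CD45RA = Σ(RAX+RABX+RABCX), CD45RO =
  Σ RX.
* **Statistics**: two-sided Mann-Whitney (exact for small untied groups) and
  Kruskal-Wallis with Dunn's Bonferroni-adjusted post-hoc tests, with
  broom-style `tidy()`/`glance()`.
* **Simulation**: generators for TCR/BCR repertoires and isoform read
  tables with complete ground truth (clone structure, spiked pathogen
  clones, injected mutations, QC artifacts), used throughout the tests.

## Worked example

Simulate a two-group study (healthy-donor-like vs diversity-contracted
"post-treatment" samples, with a 10% EBV-associated spike), then run QC →
clonotypes → diversity → annotation:

```r
library(repclone)
library(dplyr)

cfg <- sim_config(seed = 1, n_cells = 1000, n_clones = 200,
                  group_scenarios = scenario_two_group(n_samples = 3),
                  pathogen_spikes = c(EBV = 0.1))
tcr   <- generate_tcr_repertoire(cfg)
pairs <- filter_paired_cells(tcr$contigs, tcr$barcodes, cell_class = "T")
asg   <- call_clonotypes(pairs)
summ  <- repertoire_summary(asg)
select(summ, sample_id, group, n_cells, n_clonotypes, shannon,
       unique_clonotype_pct, gini)
#> # A tibble: 6 × 7
#>   sample_id group n_cells n_clonotypes shannon unique_clonotype_pct  gini
#>   <chr>     <chr>   <int>        <int>   <dbl>                <dbl> <dbl>
#> 1 CAR_S1    CAR       922           21    1.24                 2.28 0.824
#> 2 CAR_S2    CAR       921           22    1.10                 2.39 0.851
#> 3 CAR_S3    CAR       922           20    1.13                 2.17 0.826
#> 4 HD_S1     HD        921           93    2.87                10.1  0.779
#> 5 HD_S2     HD        922           93    2.92                10.1  0.774
#> 6 HD_S3     HD        921           93    2.84                10.1  0.787
```

Roughly 8% of cells fail QC (injected chain-dropout and GEX-dropout
artifacts), the contracted group's entropy drops from ≈2.9 to ≈1.2 nats and
its Gini rises — the expected diversity-contraction signature. The spiked
EBV clones are recovered at their injected frequency:

```r
pathogen_metrics(annotate_cells(pairs, tcr$pathogen_db), asg, pathogens = "EBV")
#> # A tibble: 6 × 6
#>   sample_id group pathogen n_matched   pct diversity
#>   <chr>     <chr> <chr>        <int> <dbl>     <dbl>
#> 1 CAR_S1    CAR   EBV             91  9.87      2.22
#> 2 CAR_S2    CAR   EBV             95 10.3       2.25
#> 3 CAR_S3    CAR   EBV             91  9.87      2.26
#> 4 HD_S1     HD    EBV             95 10.3       2.24
#> 5 HD_S2     HD    EBV             89  9.65      2.26
#> 6 HD_S3     HD    EBV             94 10.2       2.25

compare_groups(rename(summ, value = shannon), test = "mann_whitney")
#> Mann-Whitney comparison of 2 groups (CAR, HD)
#>   statistic = 0, p = 0.1
```

(p = 0.1 is the smallest attainable two-sided exact p at 3 vs 3.)
`run_pipeline()` chains the same stages — plus BCR clustering and SHM when a
B-cell simulation or dataset is supplied — and writes one TSV per metric
family with a JSON manifest. `plot_lorenz()`, `plot_shannon()` and
`plot_expansion_bins()` draw the standard repertoire figures.

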