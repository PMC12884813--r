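---
title: "Methods: paired-chain repertoire clonotyping, diversity and annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-chain repertoire clonotyping, diversity and annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repclone)
library(dplyr)
```

repclone analyses paired-chain single-cell immune-repertoire data — TCR
(alpha/beta) and BCR (heavy/light) V(D)J contigs — from contig tables to
per-sample diversity statistics, pathogen-associated TCR annotation, somatic
hypermutation (SHM) quantification and CD45RA/RO isoform totals. This
vignette documents the models and conventions behind each stage, the
parameters that matter, and what the synthetic-data generator does and does
not emulate.

## Quality filtering and chain pairing

Three filters produce the analysis-ready cell set:

1. **Both chains required.** A T cell must carry a TRA and a TRB contig; a B
   cell an IGH contig plus one light chain (IGK or IGL). Single-chain cells
   are discarded.
2. **Dominant chain per class.** When a barcode carries several contigs of
   the same chain class, the one with the highest UMI count is kept; ties
   break by read count, then by lexicographically smallest CDR3 nucleotide
   sequence. The last tie-break is arbitrary but total, which makes
   `resolve_chains()` invariant under permutation of its input — the same
   cell always resolves to the same chain. IGK and IGL compete within a
   single "light" class, so a dual-light-chain cell keeps its
   better-supported light chain rather than being dropped.
3. **Transcriptome concordance.** Only barcodes present in the transcriptome
   (GEX) barcode table are retained; that table also carries the sample and
   group labels.

Non-productive contigs are parsed but excluded before pairing by default
(`require_productive = TRUE`); pathogen matching and SHM both presuppose
productive rearrangements. Barcodes are opaque strings end to end — no
`-1`-suffix stripping — so GEX joins can never silently mismatch.

## Clonotype definitions

**TCR (strict).** Two T cells share a clonotype iff they are identical in
the CDR3 nucleotide sequence *and* the V, D, J and C gene calls of both
chains. Missing D/C calls become empty strings, so absent compares equal to
absent. Any single-nucleotide CDR3 difference, or any differing gene call,
separates clonotypes.

**BCR (similarity clustering).** B-cell lineages diversify by SHM, so exact
matching undercounts clones. Within each sample and chain class, two chains
are linked iff they share the V gene call and

$$\mathrm{sim}(s,t) \;=\; 1 - \frac{\mathrm{Levenshtein}(s,t)}{(|s|+|t|)/2} \;\ge\; 0.85,$$

computed on CDR3 nucleotide sequences. Clusters are the connected components
of this graph — single linkage, i.e. transitive closure — because
intermediate mutants legitimately bridge more distant members of one
lineage; complete linkage would split them. The similarity is used exactly
as defined: it is 1 iff the sequences are equal and may be negative for
very different lengths (no clamping). A cell's clonotype is the pair
(heavy-chain cluster, light-chain cluster) by default; `bcr_chains =
"heavy"` restricts keying to the heavy chain for comparison with
heavy-only conventions. At `threshold = 1` the procedure degenerates to
exact (V gene, CDR3) grouping, a property the test suite checks.

The quadratic distance computation is confined to (sample, V gene) blocks —
chains with different V genes can never link — and the edit distance itself
is implemented in C++ (`src/levenshtein.cpp`), with `utils::adist` and a
plain-R dynamic-programming implementation serving as independent oracles in
the tests.

## Diversity and clonality statistics

All statistics are computed per sample from clonotype relative frequencies
$X_i = \text{size}_i / \text{cells in sample}$:

* **Shannon entropy** $-\sum_i X_i \ln X_i$ (natural log, no normalization
  by $\ln n$): 0 for a monoclonal sample, $\ln n$ for $n$ even clonotypes.
* **Expansion bins**, lower-exclusive/upper-inclusive:
  Hyperexpanded $(0.1, 1]$, Large $(0.01, 0.1]$, Medium $(0.001, 0.01]$,
  Small $(10^{-4}, 0.001]$, Rare $(0, 10^{-4}]$. Boundary values land in the
  lower-named bin (e.g. $X = 0.1$ is Large).
* **Lorenz curve and Gini.** Clonotypes sorted ascending by size; point $k$
  is $(k/n,\ \sum_{i\le k}\text{size}_i / \sum\text{size})$, prepended with
  $(0,0)$. The Gini index is one minus twice the trapezoidal area under the
  curve; on the node set used here this equals the mean-absolute-difference
  Gini exactly, which the tests verify to $10^{-9}$.
* **Unique-clonotype percentage** $100\,n_\text{clonotypes}/n_\text{cells}$,
  and singleton (size 1) versus clonal (size > 1) tallies.

Group-level curves are summarized by the per-group median. No
rarefaction or subsampling normalization is applied; sample sizes are
reported alongside so users can judge comparability (a `repertoire_summary`
row carries `n_cells` explicitly).

## Pathogen-associated TCR annotation

A T cell is annotated with pathogen $P$ when the amino-acid CDR3 of either
chain exactly equals a reference entry for $P$ on the same chain (TRA
against alpha entries, TRB against beta entries; case-insensitive). This is
deliberate single-chain, exact matching: paired-chain specificity data are
scarce, and exact matching minimizes background at the price of
sensitivity, so the results are *pathogen associations*, not proven
specificities. Options: `require_v_gene` additionally requires the entry's
V gene (when recorded) to equal the cell's V call; `max_mismatch = 1`
enables Hamming-1 matching for sensitivity analyses (off by default); the
database is restricted to one host species (default `"HomoSapiens"`). HLA
restriction is not modelled.

Per sample and pathogen, the package reports the percentage of QC-passing
T cells annotated (a cell matching several pathogens counts once per
pathogen, so percentages can sum above 100 across pathogens) and the Shannon
entropy of the annotated subset over its renormalized clonotype
frequencies; an empty subset has percentage 0 and missing diversity.

## Somatic hypermutation

The SHM computation is this package's own definition (upstream tools vary
and rarely document theirs): the observed V-region sequence is aligned to
the germline V segment of its gene call with an end-free overlap alignment
(match +1, mismatch −1, linear gap −2, terminal gaps free), and

* `mutation_count` = substitutions + one event per contiguous internal
  indel run (a 3-nt insertion is one event, not three);
* `aligned_length` = germline positions covered by the alignment;
* `frequency` = 100 · mutation_count / aligned_length.

Two consequences of alignment-based counting are worth knowing.
Substitutions at the outermost germline positions are clipped rather than
mismatched (end-free ends are free), so they are unobservable; the
simulator therefore leaves the two outermost positions on each end
unmutated. And a dense run of adjacent substitutions can be re-explained by
the aligner as a short indel pair with fewer events — the test suite
tolerates this rare, legitimate discrepancy (≤ 2% of cells at a 2% per-site
rate) rather than forcing per-cell equality. Distribution-level recovery is
exact within sampling error: mean frequency matches the injected per-site
rate within 3 standard errors for rates 0.005–0.05.

SHM is computed on the heavy chain by default (the dominant signal);
`chain = "light"` is available. Isotype usage is a simple tally of
heavy-chain constant-gene calls.

## CD45 isoform aggregation

The six 5'-end CD45 isoforms are defined by their variable exons
(4 ↔ A, 5 ↔ B, 6 ↔ C): RAX = {4}, RABX = {4,5}, RBX = {5}, RBCX = {5,6},
RABCX = {4,5,6}, RX = ∅; exon 7 is constitutive. A read's exon
presence/absence evidence maps to a probability vector by splitting unit
mass uniformly over the isoforms compatible with every observation
(configurable prior weights are accepted; the uniform prior is the default
because no abundance information is available at the read level). Evidence
incompatible with all six isoforms yields a zero vector with a warning. Per
barcode, CD45RA = Σ(RAX + RABX + RABCX) and CD45RO = Σ RX over reads.
Pre-computed per-read probability tables from an upstream quantifier are
accepted directly, making the aggregation usable on real output without the
exon-evidence model.

## Group comparisons

Unpaired two-group comparisons use the two-sided Mann-Whitney test: exact
enumeration when both groups have ≤ 8 untied values, otherwise the normal
approximation with tie correction. Three or more groups use Kruskal-Wallis
with Dunn's pairwise post-hoc z tests (tie-corrected); the pairwise
p-values are Bonferroni-adjusted, the most conservative of the adjustments
conventionally paired with Dunn's test. Results carry broom-style `tidy()`
(pairwise table) and `glance()` (overall test) methods.

## The synthetic-data generator

Restricted-access patient data cannot ship with an analysis package, so
every stage is validated against `generate_tcr_repertoire()` /
`generate_bcr_repertoire()` / `generate_isoform_reads()`, which emulate the
statistical structure the pipeline measures and record complete ground
truth. Per sample:

* **Clone sizes** follow a power-law (weights $i^{-1.5}$ by default),
  geometric, or uniform law; the uniform law allocates cells evenly and
  deterministically so its Shannon entropy has the closed form $\ln k$,
  which the pipeline must reproduce to $10^{-9}$.
* **Group scenarios** scale the clone count (`diversity_multiplier`; 1.0 vs
  0.3 emulates the healthy-versus-post-treatment diversity contraction) and
  the size-law skew (`expansion_boost`).
* **Pathogen spikes**: a configured fraction of cells belongs to clones
  whose TRB CDR3 amino-acid sequence is copied from a database entry and
  back-translated with a fixed codon table (first codon per residue), so
  amino-acid matching is exact by construction while nucleotide-level keys
  stay clone-specific.
* **BCR clones are recoverable by construction**: founder CDR3s are
  rejection-sampled below 0.7 similarity to any same-V founder, and members
  stay within $\lfloor 0.075\,L\rfloor$ substitutions of the founder, so
  within-clone pairs sit at similarity ≥ 0.85 and cross-clone pairs
  strictly below it (triangle-inequality bound); 0.85-clustering then
  recovers the true partition with adjusted Rand index 1.
* **Technical artifacts** at configurable rates: chain dropout (cell loses
  one chain — must fail QC), spurious extra chains with strictly lower UMI
  than the true chain (must survive QC via chain resolution), and barcodes
  absent from the GEX table (must fail QC). The truth table records each
  flag and the expected QC outcome per cell.

Defaults (2000 cells, 200 clones per sample, power-law 1.5, 5% dropout, 5%
extra chains, 3% GEX dropout, SHM rate 0.02) are one realistic
peripheral-blood-like setting, fixed once. What the generator does **not**
emulate: V(D)J recombination biology (no junctional machinery or selection),
allele-level gene calls, sequencing error in CDR3s, clonal lineage trees, or
isotype switching dynamics. Passing tests therefore demonstrate the
*statistics* are computed correctly and recover known parameters, not that
biological inference on real data is automatically valid.

## Numerical and design notes

* Frequencies handed to `shannon_entropy()` must sum to 1 within $10^{-6}$;
  zero frequencies are dropped before summation. Bin boundaries are applied
  exactly as printed (upper-inclusive).
* Clonotype identifiers are assigned deterministically (descending size,
  then lexicographic key), and every pipeline stage is a pure function of
  its inputs, so a fixed simulator seed makes entire runs byte-identical —
  `run_pipeline()` output files hash equal across repeats.
* Test problem sizes (hundreds of cells per sample, 100-seed ordering
  studies, 2000-replicate null calibrations) were chosen to make sampling
  error small relative to the effects being checked while keeping the suite
  quick on a single CPU.
* Known limitations: no rarefaction-based diversity normalization, no
  epitope-level specificity modelling, no lineage-tree reconstruction, no
  splice-aware alignment for CD45 (the package consumes exon evidence or
  upstream probabilities).

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_cells = 1000, n_clones = 200,
                  group_scenarios = scenario_two_group(n_samples = 3),
                  pathogen_spikes = c(EBV = 0.1))
tcr <- generate_tcr_repertoire(cfg)
bcr <- generate_bcr_repertoire(sim_config(seed = 2, n_cells = 400, n_clones = 50))
res <- run_pipeline(tcr = tcr, bcr = bcr, out_dir = "run1", seed = 1)
res$tcr$summary
plot_lorenz(lorenz_by_sample(res$tcr$assignments))
```
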