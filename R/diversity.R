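#' Shannon entropy of clonotype frequencies
#'
#' Natural-log Shannon diversity, `-sum(p * log(p))` over clonotype relative
#' frequencies: 0 for a monoclonal repertoire, `log(n)` for `n` equally
#' frequent clonotypes. Zero frequencies are dropped before summation.
#'
#' @param frequencies Numeric vector of non-negative frequencies summing to 1
#'   (within `tol`).
#' @param tol Tolerance on the sum-to-one check.
#' @return Shannon entropy in nats.
#' @export
shannon_entropy <- function(frequencies, tol = 1e-6) {
  if (any(frequencies < 0)) {
    abort("frequencies must be non-negative", class = "repclone_parameter_error")
  }
  frequencies <- frequencies[frequencies > 0]
  if (abs(sum(frequencies) - 1) > tol) {
    abort(sprintf("frequencies sum to %.8f, not 1", sum(frequencies)),
          class = "repclone_parameter_error")
  }
  -sum(frequencies * log(frequencies))
}

#' Clonal-expansion homeostasis bins
#'
#' Classifies each clonotype by its relative frequency X into the standard
#' homeostasis bins, with lower-exclusive / upper-inclusive boundaries:
#' Hyperexpanded (0.1 < X <= 1), Large (0.01 < X <= 0.1), Medium
#' (0.001 < X <= 0.01), Small (1e-4 < X <= 0.001), Rare (0 < X <= 1e-4).
#' Boundary values land in the lower-named bin (e.g. X = 0.1 is Large).
#'
#' @param frequencies Numeric vector of relative frequencies in (0, 1].
#' @return Factor of bin labels (levels Rare ... Hyperexpanded), same length
#'   as the input.
#' @export
expansion_bins <- function(frequencies) {
  if (any(frequencies <= 0 | frequencies > 1)) {
    abort("relative frequencies must lie in (0, 1]",
          class = "repclone_parameter_error")
  }
  cut(frequencies,
      breaks = c(0, 1e-4, 1e-3, 1e-2, 0.1, 1),
      labels = expansion_bin_levels,
      right = TRUE, include.lowest = FALSE)
}

expansion_bin_levels <- c("Rare", "Small", "Medium", "Large", "Hyperexpanded")

#' Lorenz curve of clonal inequality
#'
#' With clonotypes sorted by ascending size, point k of the curve is
#' (k / n_clonotypes, cumulative cell fraction of the k smallest clonotypes),
#' prepended with (0, 0). A perfectly even repertoire lies on the diagonal;
#' clonal expansion bows the curve below it.
#'
#' @param sizes Positive integer clonotype sizes (cell counts).
#' @return Tibble with columns `frac_clonotypes`, `frac_cells`.
#' @seealso [gini_index()] for the summary scalar.
#' @export
lorenz_curve <- function(sizes) {
  if (length(sizes) == 0) {
    abort("at least one clonotype is required", class = "repclone_parameter_error")
  }
  if (any(sizes <= 0)) {
    abort("clonotype sizes must be positive", class = "repclone_parameter_error")
  }
  sizes <- sort(sizes)
  n <- length(sizes)
  tibble(
    frac_clonotypes = c(0, seq_len(n) / n),
    frac_cells      = c(0, cumsum(sizes) / sum(sizes))
  )
}

#' Gini index of clonal inequality
#'
#' One minus twice the trapezoidal area under the Lorenz curve: 0 for equal
#' clone sizes, approaching 1 when a single clone dominates.
#'
#' @param sizes Positive clonotype sizes.
#' @return Gini index in \[0, 1).
#' @export
gini_index <- function(sizes) {
  pts <- lorenz_curve(sizes)
  area <- sum(diff(pts$frac_clonotypes) *
                (head(pts$frac_cells, -1) + pts$frac_cells[-1]) / 2)
  1 - 2 * area
}

#' Percentage of unique clonotypes
#'
#' `100 * n_clonotypes / n_cells`: 100 when every cell is its own clonotype,
#' small when the repertoire is dominated by expanded clones.
#'
#' @param n_clonotypes,n_cells Counts with `n_cells >= n_clonotypes >= 1`.
#' @return Percentage in (0, 100].
#' @export
unique_clonotype_pct <- function(n_clonotypes, n_cells) {
  if (any(n_cells <= 0)) {
    abort("n_cells must be positive", class = "repclone_parameter_error")
  }
  if (any(n_clonotypes > n_cells) || any(n_clonotypes < 1)) {
    abort("need n_cells >= n_clonotypes >= 1", class = "repclone_parameter_error")
  }
  100 * n_clonotypes / n_cells
}

#' Per-sample repertoire summary
#'
#' Bundles the repertoire-level statistics for each sample: cell and
#' clonotype counts, Shannon entropy, unique-clonotype percentage, Gini
#' index, expansion-bin counts, and singleton (size 1) versus clonal
#' (size > 1) tallies.
#'
#' @param assignments Cell-level clonotype assignments from
#'   [call_clonotypes()].
#' @return One row per sample with columns `sample_id`, `group`, `n_cells`,
#'   `n_clonotypes`, `shannon`, `unique_clonotype_pct`, `gini`,
#'   `n_singleton`, `n_clonal`, and one `n_<bin>` column per expansion bin.
#' @export
repertoire_summary <- function(assignments) {
  clones <- summarise_clonotypes(assignments)
  clones |>
    group_by(.data$sample_id, .data$group) |>
    group_modify(function(cl, key) {
      bins <- table(expansion_bins(cl$freq))
      out <- tibble(
        n_cells = sum(cl$size),
        n_clonotypes = nrow(cl),
        shannon = shannon_entropy(cl$freq),
        unique_clonotype_pct = unique_clonotype_pct(nrow(cl), sum(cl$size)),
        gini = gini_index(cl$size),
        n_singleton = sum(cl$size == 1),
        n_clonal = sum(cl$size > 1)
      )
      for (b in expansion_bin_levels) {
        out[[paste0("n_", tolower(b))]] <- as.integer(bins[[b]])
      }
      out
    }) |>
    ungroup()
}

#' Per-sample Lorenz curves
#'
#' @param assignments Cell-level clonotype assignments.
#' @return Long tibble of Lorenz points with `sample_id`, `group`,
#'   `frac_clonotypes`, `frac_cells`.
#' @export
lorenz_by_sample <- function(assignments) {
  summarise_clonotypes(assignments) |>
    group_by(.data$sample_id, .data$group) |>
    group_modify(~ lorenz_curve(.x$size)) |>
    ungroup()
}

#' Isotype usage tally
#'
#' Counts cells per heavy-chain constant-gene call (isotype) per sample.
#'
#' @param pairs Paired-cell tibble of B cells.
#' @return Tibble `sample_id`, `group`, `c_gene`, `n`.
#' @export
isotype_counts <- function(pairs) {
  pairs |>
    count(.data$sample_id, .data$group, c_gene = .data$a_c_gene) |>
    arrange(.data$sample_id, desc(.data$n))
}
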