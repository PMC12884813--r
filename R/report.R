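#' Compare a repertoire metric between groups
#'
#' Two-sided nonparametric group comparisons as used for unpaired repertoire
#' metrics: the Mann-Whitney (Wilcoxon rank-sum) test for two groups — exact
#' enumeration when both groups have at most 8 untied values, the normal
#' approximation with tie correction otherwise — and the Kruskal-Wallis test
#' with Dunn's pairwise post-hoc comparisons (Bonferroni-adjusted) for three
#' or more groups.
#'
#' @param data A data frame with one row per sample.
#' @param value,group Column names (unquoted) holding the metric value and
#'   the group label. Defaults `value` and `group`.
#' @param test `"mann_whitney"` or `"kruskal_wallis_dunn"`.
#' @return A `group_comparison` object; see [tidy.group_comparison()] and
#'   [glance.group_comparison()].
#' @examples
#' d <- data.frame(group = rep(c("HD", "CAR"), each = 3),
#'                 value = c(1, 2, 3, 10, 11, 12))
#' compare_groups(d, test = "mann_whitney")$p_value
#' @export
compare_groups <- function(data, value = value, group = group,
                           test = c("mann_whitney", "kruskal_wallis_dunn")) {
  test <- match.arg(test)
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  if (anyNA(v) || anyNA(g)) {
    keep <- !is.na(v) & !is.na(g)
    v <- v[keep]; g <- g[keep]
  }
  groups <- unique(g)
  ns <- table(g)
  if (test == "mann_whitney") {
    if (length(groups) != 2) {
      abort("mann_whitney requires exactly 2 groups",
            class = "repclone_parameter_error")
    }
    x <- v[g == groups[1]]
    y <- v[g == groups[2]]
    has_ties <- anyDuplicated(c(x, y)) > 0
    use_exact <- length(x) <= 8 && length(y) <= 8 && !has_ties
    ht <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                  correct = !use_exact)
    )
    res <- list(test = test, groups = groups, n = as.list(ns),
                statistic = unname(ht$statistic), p_value = ht$p.value,
                exact = use_exact,
                pairwise = tibble(group1 = groups[1], group2 = groups[2],
                                  statistic = unname(ht$statistic),
                                  p_value = ht$p.value, p_adjusted = ht$p.value))
  } else {
    if (length(groups) < 3) {
      abort("kruskal_wallis_dunn requires at least 3 groups",
            class = "repclone_parameter_error")
    }
    kw <- kruskal.test(v, factor(g))
    res <- list(test = test, groups = groups, n = as.list(ns),
                statistic = unname(kw$statistic), p_value = kw$p.value,
                exact = FALSE, pairwise = dunn_pairwise(v, g))
  }
  res$values <- split(v, g)
  structure(res, class = "group_comparison")
}

# Dunn's post-hoc z tests on mean ranks with tie correction; Bonferroni
# adjustment over all pairwise comparisons.
dunn_pairwise <- function(v, g) {
  N <- length(v)
  r <- rank(v)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  combs <- utils::combn(names(mean_rank), 2)
  out <- purrr::map(seq_len(ncol(combs)), function(i) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- (mean_rank[[g1]] - mean_rank[[g2]]) / se
    tibble(group1 = g1, group2 = g2, statistic = z,
           p_value = 2 * pnorm(-abs(z)))
  }) |> list_rbind()
  mutate(out, p_adjusted = pmin(.data$p_value * n(), 1))
}

#' @describeIn compare_groups Tidy the pairwise comparison table.
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$pairwise
}

#' @describeIn compare_groups One-row summary of the overall test.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    method = if (x$test == "mann_whitney") {
      if (x$exact) "Mann-Whitney (exact)" else "Mann-Whitney (normal approximation)"
    } else "Kruskal-Wallis",
    statistic = x$statistic,
    p.value = x$p_value,
    n_groups = length(x$groups),
    n_total = sum(unlist(x$n))
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s comparison of %d groups (%s)\n",
              if (x$test == "mann_whitney") "Mann-Whitney" else "Kruskal-Wallis + Dunn",
              length(x$groups), paste(x$groups, collapse = ", ")))
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  if (x$test == "kruskal_wallis_dunn") {
    print(x$pairwise)
  }
  invisible(x)
}
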