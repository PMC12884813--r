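#' Lorenz curve plot
#'
#' One curve per sample, coloured by group, with the equality diagonal.
#'
#' @param lorenz Long tibble from [lorenz_by_sample()].
#' @return A ggplot object.
#' @export
plot_lorenz <- function(lorenz) {
  ggplot2::ggplot(lorenz, ggplot2::aes(.data$frac_clonotypes, .data$frac_cells,
                                       group = .data$sample_id,
                                       colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Cumulative clonotype fraction",
                  y = "Cumulative cell fraction", colour = "Group") +
    ggplot2::theme_minimal()
}

#' Shannon diversity boxplot by group
#'
#' @param summary Per-sample tibble from [repertoire_summary()].
#' @return A ggplot object.
#' @export
plot_shannon <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(.data$group, .data$shannon,
                                        fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.15, size = 1.5) +
    ggplot2::labs(x = NULL, y = "Shannon entropy (nats)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Stacked expansion-bin composition per sample
#'
#' @param summary Per-sample tibble from [repertoire_summary()].
#' @return A ggplot object.
#' @export
plot_expansion_bins <- function(summary) {
  long <- summary |>
    select("sample_id", "group", starts_with("n_")) |>
    select(-any_of(c("n_cells", "n_clonotypes", "n_singleton", "n_clonal"))) |>
    pivot_longer(starts_with("n_"), names_to = "bin", values_to = "n") |>
    mutate(bin = factor(sub("^n_", "", .data$bin),
                        levels = tolower(expansion_bin_levels)))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$n, fill = .data$bin)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::facet_grid(~ group, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "Clonotype fraction", fill = "Expansion bin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.group_comparison <- function(object, ...) {
  d <- purrr::imap(object$values, ~ tibble(group = .y, value = .x)) |> list_rbind()
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$value, fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.15) +
    ggplot2::labs(subtitle = sprintf("p = %.3g", object$p_value),
                  x = NULL, y = "value") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
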