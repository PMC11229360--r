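# Plain ggplot2 views of the census results.

#' Bar chart of per-family locus counts
#'
#' @param object a `census_counts` tibble from [count_families()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.census_counts <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$family, -.data$n_loci),
                               y = .data$n_loci)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "loci with family",
                  title = "Effector family abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of family co-occurrence counts
#'
#' @param cooc result of [cooccurrence_matrix()].
#' @return a ggplot.
#' @export
plot_cooccurrence <- function(cooc) {
  M <- cooc$matrix
  df <- as_tibble(as.data.frame(as.table(M), stringsAsFactors = FALSE)) |>
    setNames(c("family1", "family2", "count")) |>
    filter(.data$family1 < .data$family2)
  ggplot2::ggplot(df, ggplot2::aes(.data$family1, .data$family2,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "loci",
                  title = "Effector co-occurrence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of UpSet-style effector configurations
#'
#' @param upset tibble from [upset_configurations()].
#' @param top show at most this many configurations.
#' @return a ggplot.
#' @export
plot_upset_configurations <- function(upset, top = 15) {
  df <- upset |>
    mutate(configuration = if_else(.data$configuration == "",
                                   "(none)", .data$configuration)) |>
    slice_max(.data$n, n = top, with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$configuration, -.data$n), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::labs(x = NULL, y = "loci",
                  title = "Effector configurations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
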