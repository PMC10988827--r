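#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an enrichment result into a one-row tibble
#'
#' @param x An `enrichment_result` from [enrich()] or [odds_ratio_wald()].
#' @param ... Unused.
#' @return Tibble with `or`, `ci_low`, `ci_high`, `p`, the four table cells
#'   and `correction_applied`.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    or = x$or, ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
    a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
    correction_applied = x$correction_applied
  )
}

#' Rounded presentation of an enrichment result
#'
#' Odds ratio and interval at one decimal, matching the conventional
#' reporting style; full precision stays in [tidy()].
#'
#' @inheritParams tidy.enrichment_result
#' @return One-row tibble with `or`, `ci_low`, `ci_high` (1 dp) and `p`.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(or = round(x$or, 1), ci_low = round(x$ci_low, 1),
                 ci_high = round(x$ci_high, 1), p = x$p)
}

#' Tidy a clustering fit into per-proband rows
#'
#' @param x A `phenoclust_fit` from [phenocluster()].
#' @param ... Unused.
#' @return The cluster assignment tibble (`proband_id`, `cluster`).
#' @export
tidy.phenoclust_fit <- function(x, ...) {
  tibble::as_tibble(x$assignment)
}

#' One-row summary of a clustering fit
#'
#' @inheritParams tidy.phenoclust_fit
#' @return Tibble with `n_probands`, `k`, `mean_similarity` (off-diagonal)
#'   and `gap_at_k`.
#' @export
glance.phenoclust_fit <- function(x, ...) {
  S <- x$similarity
  tibble::tibble(
    n_probands = nrow(S),
    k = x$k,
    mean_similarity = mean(S[upper.tri(S)]),
    gap_at_k = x$gap$gap[x$gap$k == x$k]
  )
}

#' Plot a gap-statistic curve
#'
#' Gap against cluster count with one-standard-error bars.
#'
#' @param object A `gap_curve` from [gap_statistic()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gap_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$se,
                                          ymax = .data$gap + .data$se)) +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "number of clusters k", y = "gap statistic") +
    ggplot2::theme_minimal()
}

#' Phenotypic-similarity heatmap ordered by the dendrogram
#'
#' Rows and columns follow the dendrogram leaf order recorded in the
#' cluster assignment, so co-clustered probands sit in contiguous blocks.
#'
#' @param object A `phenoclust_fit` from [phenocluster()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phenoclust_fit <- function(object, ...) {
  ord <- attr(object$assignment, "leaf_order")
  df <- tibble::as_tibble(object$similarity, rownames = "row") %>%
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "similarity") %>%
    dplyr::mutate(row = factor(.data$row, levels = ord),
                  col = factor(.data$col, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                  high = "#b2182b", midpoint = 0.5,
                                  limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Per-cluster phenotype frequency grid
#'
#' Tile plot of [cluster_term_frequencies()], the tabular analogue of a
#' phenotype-grid figure.
#'
#' @param fit A `phenoclust_fit`.
#' @param graph Optional ontology used to label terms by name.
#' @return A ggplot.
#' @export
plot_term_grid <- function(fit, graph = NULL) {
  tf <- fit$term_frequencies
  if (!is.null(graph)) {
    tf <- dplyr::mutate(tf, term_id = unname(graph$name[.data$term_id]))
  }
  ggplot2::ggplot(tf, ggplot2::aes(x = .data$term_id,
                                   y = factor(.data$cluster),
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey95", high = "#b2182b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "cluster", fill = "frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
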