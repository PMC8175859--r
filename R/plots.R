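#' Plot the top of a differential ranking
#'
#' Horizontal bar chart of the per-node GFS difference for the top-ranked
#' nodes, largest difference on top.
#'
#' @param object a [differential_ranking()].
#' @param n_top number of nodes shown.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot differential_ranking
#' @export
autoplot.differential_ranking <- function(object, n_top = sum(object$top), ...) {
  df <- utils::head(as_tibble(object), n_top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$delta,
    y = stats::reorder(.data$node, .data$delta)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = expression(Delta * "GFS (group A - group B)"),
      y = NULL,
      title = sprintf("Top %d nodes by GFS difference", n_top)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a steady-state probability matrix
#'
#' Rows are start nodes, columns the stationary probability of finding the
#' walker at each node; log10 fill since restart concentrates mass on the
#' diagonal.
#'
#' @param object a [steady_state()] matrix.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot steady_state_matrix
#' @export
autoplot.steady_state_matrix <- function(object, ...) {
  M <- unclass(object)
  df <- tidyr::expand_grid(
    from = factor(rownames(M), levels = rownames(M)),
    to = factor(colnames(M), levels = colnames(M))
  )
  df$pi <- as.vector(t(M))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from, fill = log10(.data$pi + 1e-12))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(log[10] ~ pi[ij])) +
    ggplot2::labs(x = "node reached", y = "start node") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Paired feature profiles of a group comparison
#'
#' Normalized feature values of both group-average networks, one facet per
#' feature, nodes ordered by the GFS-difference ranking.
#'
#' @param object a [compare_groups()] result.
#' @param n_top number of top-ranked nodes shown.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, n_top = sum(object$ranking$top), ...) {
  keep <- object$ranking$node[object$ranking$rank <= n_top]
  long <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(object$features_a), group = "A"),
    dplyr::mutate(as_tibble(object$features_b), group = "B")
  ) |>
    dplyr::filter(.data$node %in% keep) |>
    tidyr::pivot_longer(dplyr::all_of(norm_cols),
      names_to = "feature", values_to = "value"
    )
  long$node <- factor(long$node, levels = rev(keep))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$value, y = .data$node,
    colour = .data$group
  )) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~feature, nrow = 1) +
    ggplot2::labs(x = "normalized feature value", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
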