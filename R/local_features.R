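#' @noRd
as_igraph <- function(g, weighted = FALSE) {
  A <- g$W
  if (!weighted) A <- (A > 0) * 1
  igraph::graph_from_adjacency_matrix(A,
    mode = "undirected", weighted = if (weighted) TRUE else NULL, diag = FALSE
  )
}

feature_tibble <- function(g, name, values) {
  out <- tibble(node = g$labels, value = as.numeric(values))
  names(out)[2] <- name
  out
}

#' Degree centrality
#'
#' For node \eqn{v_i}, \eqn{C_D(v_i) = d(v_i) / (n - 1)} where \eqn{d(v_i)}
#' is the number of distinct neighbours joined to \eqn{v_i} by a
#' positive-weight edge. Weights are not summed: a single heavy edge counts
#' as one neighbour.
#'
#' @param g a [weighted_graph()] with at least 2 nodes.
#' @return A tibble with columns `node` and `c_d` (values in `[0, 1]`).
#' @export
degree_centrality <- function(g) {
  n <- n_nodes(g)
  if (n < 2) abort("degree centrality needs at least 2 nodes.")
  d <- rowSums(g$W > 0)
  feature_tibble(g, "c_d", d / (n - 1))
}

#' Betweenness centrality
#'
#' For node \eqn{v_i}, the sum over unordered pairs \eqn{\{v_s, v_t\}} (with
#' \eqn{s \ne t}, \eqn{i \notin \{s, t\}}) of the fraction of shortest
#' \eqn{s}–\eqn{t} paths passing through \eqn{v_i}. Pairs in different
#' components contribute 0. By default paths are geodesics of the binarized
#' skeleton (unit edge lengths); with `weighted = TRUE` edge length is
#' `1/w`, so heavier fiber bundles are shorter.
#'
#' @inheritParams degree_centrality
#' @param weighted use `1/w` edge lengths instead of unit lengths.
#' @return A tibble with columns `node` and `c_b`.
#' @export
betweenness_centrality <- function(g, weighted = FALSE) {
  if (n_nodes(g) < 2) abort("betweenness centrality needs at least 2 nodes.")
  ig <- as_igraph(g, weighted = weighted)
  w <- if (weighted) 1 / igraph::E(ig)$weight else NA
  b <- igraph::betweenness(ig, directed = FALSE, weights = w, normalized = FALSE)
  feature_tibble(g, "c_b", b)
}

#' Closeness centrality
#'
#' On a connected graph, \eqn{C_c(v_i) = (n-1) / \sum_j d(v_j, v_i)}: the
#' normalized reciprocal of the total shortest-path distance to all other
#' nodes. On disconnected graphs the reachable-set form is used: with `r`
#' nodes reachable from \eqn{v_i},
#' \eqn{C_c = \frac{r-1}{\sum d} \cdot \frac{r-1}{n-1}}, which reduces to
#' the plain formula when the graph is connected and gives isolated nodes 0.
#'
#' @inheritParams betweenness_centrality
#' @return A tibble with columns `node` and `c_c` (in `[0, 1]` for unit
#'   edge lengths).
#' @export
closeness_centrality <- function(g, weighted = FALSE) {
  n <- n_nodes(g)
  if (n < 2) abort("closeness centrality needs at least 2 nodes.")
  ig <- as_igraph(g, weighted = weighted)
  w <- if (weighted) 1 / igraph::E(ig)$weight else NA
  D <- igraph::distances(ig, weights = w)
  cc <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d)
    r <- sum(reach)
    if (r == 0) return(0)
    (r / sum(d[reach])) * (r / (n - 1))
  }, numeric(1))
  feature_tibble(g, "c_c", cc)
}

#' Number of maximal cliques per node
#'
#' Counts, for each node, the maximal cliques (complete subgraphs not
#' contained in any larger complete subgraph) of the positive-weight
#' skeleton that contain it. An isolated node forms its own singleton
#' maximal clique and scores 1.
#'
#' @inheritParams degree_centrality
#' @param max_cliques safety cap on the number of maximal cliques
#'   (enumeration is exponential in the worst case); exceeding it is an
#'   error.
#' @return A tibble with columns `node` and `n_mc` (nonnegative integers).
#' @export
maximal_clique_counts <- function(g, max_cliques = 1e6) {
  ig <- as_igraph(g, weighted = FALSE)
  n_cl <- igraph::count_max_cliques(ig, min = 1)
  if (n_cl > max_cliques) {
    abort(sprintf(
      "graph has %d maximal cliques, exceeding the cap of %g.",
      n_cl, max_cliques
    ), class = "gfsnet_error_clique_cap")
  }
  cl <- igraph::max_cliques(ig, min = 1)
  counts <- tabulate(unlist(lapply(cl, as.integer)), nbins = n_nodes(g))
  feature_tibble(g, "n_mc", counts)
}
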