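#' Min-max rescale a feature vector to [0, 1]
#'
#' `(x - min) / (max - min)`. A constant vector has no range to rescale;
#' it maps to all zeros (with a warning) so it contributes nothing to a
#' composite score rather than a spurious constant. Constancy is judged
#' with a relative tolerance (range below `1e-12` of the largest
#' magnitude), so floating-point noise on an analytically constant feature
#' is not blown up to the full unit interval.
#'
#' @param x finite numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_minmax <- function(x) {
  if (!all(is.finite(x))) abort("feature values must be finite.")
  rng <- range(x)
  if (rng[2] - rng[1] <= 1e-12 * max(abs(rng), 1e-300)) {
    warn("constant feature vector; normalized to all zeros.")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Compute the five local features of a network
#'
#' One call per network: degree centrality (`c_d`), betweenness (`c_b`),
#' closeness (`c_c`), maximal-clique counts (`n_mc`), and 2hop-connectivity
#' (`s_2hop`) from the steady-state matrix of the 2-hop restart walk. Each
#' raw column is min-max normalized into an `n`-prefixed column
#' (`nc_d` ... `ns_2hop`).
#'
#' @param g a cleaned [weighted_graph()].
#' @param c continuation probability of the 2-hop walk.
#' @param alpha_mode,scalar_alpha1 passed to [transition_model()].
#' @param weighted_paths use `1/w` edge lengths for betweenness/closeness.
#' @param s2hop_mode passed to [s2hop_scores()].
#' @return A `feature_table` tibble: `node`, five raw columns, five
#'   normalized columns.
#' @export
node_features <- function(g, c = 0.85,
                          alpha_mode = c("per_node", "scalar"),
                          scalar_alpha1 = NULL,
                          weighted_paths = FALSE,
                          s2hop_mode = c("column_sum", "row_sum")) {
  alpha_mode <- match.arg(alpha_mode)
  s2hop_mode <- match.arg(s2hop_mode)
  model <- transition_model(g, alpha_mode = alpha_mode, scalar_alpha1 = scalar_alpha1)
  Pi <- steady_state(model, c = c)
  tab <- degree_centrality(g) |>
    dplyr::left_join(betweenness_centrality(g, weighted = weighted_paths), by = "node") |>
    dplyr::left_join(closeness_centrality(g, weighted = weighted_paths), by = "node") |>
    dplyr::left_join(maximal_clique_counts(g), by = "node") |>
    dplyr::left_join(s2hop_scores(Pi, mode = s2hop_mode), by = "node")
  constant <- character(0)
  norm <- withCallingHandlers(
    dplyr::mutate(tab, dplyr::across(
      c("c_d", "c_b", "c_c", "n_mc", "s_2hop"),
      normalize_minmax,
      .names = "n{.col}"
    )),
    warning = function(w) {
      constant <<- c(constant, "feature")
      invokeRestart("muffleWarning")
    }
  )
  if (length(constant) > 0) {
    warn(sprintf("%d constant feature column(s) normalized to zeros.", length(constant)))
  }
  class(norm) <- c("feature_table", class(norm))
  norm
}

feature_cols <- c("c_d", "c_b", "c_c", "n_mc", "s_2hop")
norm_cols <- paste0("n", feature_cols)

check_gfs_weights <- function(weights) {
  if (length(weights) != 5) {
    abort("GFS needs exactly 5 weights (one per feature).")
  }
  if (any(weights < 0)) abort("GFS weights must be nonnegative.")
  s <- sum(weights)
  if (s <= 0) abort("GFS weights must not all be zero.")
  if (abs(s - 1) > 1e-12) weights <- weights / s
  weights
}

#' Global Feature Score
#'
#' Per-node convex combination of the five normalized features:
#' \deqn{GFS(v_i) = w_1 NC_D + w_2 NC_B + w_3 NC_C + w_4 NN_{MC} + w_5 NS_{2hop}.}
#' Default weights are 1/5 each; [fit_gfs_weights()] estimates them from an
#' external cognitive score instead.
#'
#' @param table a [node_features()] table.
#' @param weights 5 nonnegative weights in feature order
#'   (`c_d`, `c_b`, `c_c`, `n_mc`, `s_2hop`); rescaled to sum to 1.
#' @return A tibble with columns `node` and `gfs` (values in `[0, 1]`).
#' @export
gfs_score <- function(table, weights = rep(1 / 5, 5)) {
  weights <- check_gfs_weights(weights)
  M <- as.matrix(table[, norm_cols])
  tibble(node = table$node, gfs = as.numeric(M %*% weights))
}

#' Fit GFS weights to an external score by nonnegative least squares
#'
#' Regresses a per-node-matched external score (e.g., a cognitive scale
#' such as the MMSE) on the five normalized features with nonnegative
#' least-squares coefficients, rescaled to sum to 1 so GFS remains a
#' convex combination. An all-zero solution (score unrelated to every
#' feature) falls back to equal weights with a warning.
#'
#' @param table a [node_features()] table.
#' @param scores numeric vector, one observation per table row (at least 6).
#' @return Named numeric weight vector of length 5 summing to 1.
#' @export
fit_gfs_weights <- function(table, scores) {
  if (length(scores) != nrow(table)) {
    abort("`scores` must have one value per node row.")
  }
  if (length(scores) < 6) abort("need at least 6 observations to fit weights.")
  M <- as.matrix(table[, norm_cols])
  w <- pracma::lsqnonneg(M, as.numeric(scores))$x
  if (sum(w) <= 0) {
    warn("nonnegative fit is identically zero; falling back to equal weights.")
    w <- rep(1 / 5, 5)
  }
  setNames(w / sum(w), feature_cols)
}

#' Rank nodes by between-group GFS difference
#'
#' `delta = gfs_a - gfs_b` per node (conventionally control minus case, so
#' nodes weakened in the case group rank first), sorted descending with a
#' 1-based dense rank. Ties are broken by input label order, so the
#' ordering is deterministic.
#'
#' @param gfs_a,gfs_b tibbles from [gfs_score()] with aligned `node` labels.
#' @param top_k optional number of top rows to flag in the `top` column.
#' @return A `differential_ranking` tibble: `node`, `gfs_a`, `gfs_b`,
#'   `delta`, `rank`, `top`, ordered by rank.
#' @export
differential_ranking <- function(gfs_a, gfs_b, top_k = 10) {
  if (!identical(gfs_a$node, gfs_b$node)) {
    abort("node labels of the two GFS tables do not match.",
      class = "gfsnet_error_labels"
    )
  }
  n <- nrow(gfs_a)
  if (top_k < 1 || top_k > n) abort("`top_k` must be between 1 and the node count.")
  delta <- gfs_a$gfs - gfs_b$gfs
  out <- tibble(
    node = gfs_a$node,
    gfs_a = gfs_a$gfs,
    gfs_b = gfs_b$gfs,
    delta = delta
  )
  ord <- order(-out$delta, seq_len(n)) # stable: label order breaks ties
  out <- out[ord, ]
  out$rank <- seq_len(n)
  out$top <- out$rank <= top_k
  class(out) <- c("differential_ranking", class(out))
  out
}

#' First canonical correlation between two variable blocks
#'
#' Finds linear composites \eqn{U = Xa}, \eqn{V = Yb} maximizing
#' \eqn{cor(U, V)} and reports the first canonical pair: correlation `rho`
#' and the loading vectors. Zero-variance columns are dropped with a
#' warning. `rho` is invariant under invertible affine transformations of
#' either block.
#'
#' @param X,Y data frames or matrices with the same number of rows
#'   (observations); at least 3 rows.
#' @return An object of class `cca_first` with elements `rho`,
#'   `x_loadings`, `y_loadings`, `n_obs`.
#' @export
cca_first <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) {
    abort("X and Y must have the same number of observations.")
  }
  if (nrow(X) < 3) abort("need at least 3 observations for CCA.")
  drop_const <- function(M, nm) {
    keep <- apply(M, 2, function(col) sd(col) > 0)
    if (!all(keep)) {
      warn(sprintf("dropping %d zero-variance column(s) from %s.", sum(!keep), nm))
    }
    M[, keep, drop = FALSE]
  }
  X <- drop_const(X, "X")
  Y <- drop_const(Y, "Y")
  if (ncol(X) == 0 || ncol(Y) == 0) abort("a block has no varying columns.")
  fit <- stats::cancor(X, Y)
  a <- fit$xcoef[, 1]
  b <- fit$ycoef[, 1]
  structure(
    list(
      rho = unname(fit$cor[1]),
      x_loadings = a,
      y_loadings = b,
      n_obs = nrow(X)
    ),
    class = "cca_first"
  )
}

#' @export
print.cca_first <- function(x, ...) {
  cat(sprintf(
    "<cca_first> first canonical correlation rho = %.4f (n = %d)\n",
    x$rho, x$n_obs
  ))
  invisible(x)
}

#' @rdname cca_first
#' @param x a `cca_first` object.
#' @param ... unused.
#' @method tidy cca_first
#' @export
tidy.cca_first <- function(x, ...) {
  tibble(
    block = c(
      rep("x", length(x$x_loadings)),
      rep("y", length(x$y_loadings))
    ),
    term = c(
      names(x$x_loadings) %||% paste0("x", seq_along(x$x_loadings)),
      names(x$y_loadings) %||% paste0("y", seq_along(x$y_loadings))
    ),
    loading = c(unname(x$x_loadings), unname(x$y_loadings))
  )
}

#' @rdname cca_first
#' @method glance cca_first
#' @export
glance.cca_first <- function(x, ...) {
  tibble(rho = x$rho, n_obs = x$n_obs)
}
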