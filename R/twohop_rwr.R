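#' Build the 2-hop transition model of a weighted network
#'
#' The one-step transition matrix is the weighted-degree row normalization
#' \eqn{P = D_G^{-1} W} with \eqn{d_i = \sum_j w_{ij}}; the two-step
#' operator is \eqn{P^2}. Rows of isolated nodes are set to the unit
#' self-vector so `P` stays row-stochastic.
#'
#' The hop-mixing fractions weight the one-step against the two-step
#' operator. In `per_node` mode, for node \eqn{v_i},
#' \eqn{\alpha_1(i) = |N_1(i)| / (|N_1(i)| + |N_2(i)|)} where \eqn{N_1(i)}
#' is the set of 1-hop neighbours and \eqn{N_2(i)} the set of nodes at
#' exactly distance 2 (excluding the node itself and its 1-hop
#' neighbours); \eqn{\alpha_2 = 1 - \alpha_1}. Nodes with no 1- or 2-hop
#' neighbours get \eqn{\alpha_1 = 1}. In `scalar` mode a single
#' `scalar_alpha1` applies to every node; `scalar_alpha1 = 1` recovers the
#' classical random walk with restart.
#'
#' Note the asymmetry, deliberate and consistent with the mixing rule: the
#' \eqn{\alpha} fractions count exact-distance-2 nodes, while the two-step
#' operator is the raw \eqn{P^2}, which includes return-to-self mass.
#'
#' @param g a cleaned [weighted_graph()].
#' @param alpha_mode `"per_node"` (default) or `"scalar"`.
#' @param scalar_alpha1 1-hop fraction in `[0, 1]`, required in scalar mode.
#' @return An object of class `transition_model`: list with `P`, `P2`,
#'   `alpha1`, `alpha2`, `labels`, `alpha_mode`.
#' @examples
#' g <- weighted_graph(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3),
#'   labels = c("a", "b", "c")
#' )
#' m <- transition_model(g)
#' m$alpha1 # a and c split 1/2-1/2; b has no exact-2-hop neighbours
#' @export
transition_model <- function(g, alpha_mode = c("per_node", "scalar"),
                             scalar_alpha1 = NULL) {
  alpha_mode <- match.arg(alpha_mode)
  W <- g$W
  n <- n_nodes(g)
  d <- rowSums(W)
  P <- W / ifelse(d > 0, d, 1)
  iso <- which(d == 0)
  for (i in iso) P[i, i] <- 1
  P2 <- P %*% P

  A <- W > 0
  if (alpha_mode == "scalar") {
    if (is.null(scalar_alpha1)) {
      abort("scalar alpha mode requires `scalar_alpha1`.")
    }
    if (scalar_alpha1 < 0 || scalar_alpha1 > 1) {
      abort("`scalar_alpha1` must be in [0, 1].")
    }
    alpha1 <- rep(scalar_alpha1, n)
  } else {
    A2 <- (A %*% A) > 0 # reachable in two steps
    alpha1 <- vapply(seq_len(n), function(i) {
      n1 <- sum(A[i, ])
      two <- A2[i, ] & !A[i, ]
      two[i] <- FALSE
      n2 <- sum(two)
      if (n1 + n2 == 0) 1 else n1 / (n1 + n2)
    }, numeric(1))
  }
  structure(
    list(
      P = P, P2 = P2, alpha1 = alpha1, alpha2 = 1 - alpha1,
      labels = g$labels, alpha_mode = alpha_mode
    ),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf(
    "<transition_model> %d states, alpha_mode = %s, mean alpha1 = %.3f\n",
    length(x$labels), x$alpha_mode, mean(x$alpha1)
  ))
  invisible(x)
}

# Row-wise hop mixture diag(alpha1) P + diag(alpha2) P^2; each row remains
# stochastic, so spectral radius <= 1 and I - cA is invertible for c < 1.
mixed_operator <- function(model) {
  model$alpha1 * model$P + model$alpha2 * model$P2
}

check_walk_args <- function(c, tol = 1e-10, max_iter = 1000L) {
  if (c < 0 || c >= 1) {
    abort("`c` (continuation probability) must satisfy 0 <= c < 1.")
  }
  if (tol <= 0) abort("`tol` must be positive.")
  if (max_iter < 1) abort("`max_iter` must be at least 1.")
  invisible(TRUE)
}

resolve_start <- function(model, start) {
  if (is.character(start)) {
    idx <- match(start, model$labels)
    if (is.na(idx)) abort(sprintf("unknown start node '%s'.", start))
    return(idx)
  }
  start <- as.integer(start)
  if (start < 1 || start > length(model$labels)) {
    abort("start index out of range.")
  }
  start
}

#' Iterate the 2-hop random walk with restart to stationarity
#'
#' Starting from the unit vector \eqn{r_0} at `start`, iterates
#' \deqn{r_{t+1} = c\,(\alpha_1 P^\top + \alpha_2 (P^2)^\top)\, r_t + (1 - c)\, r_0}
#' until the L1 change falls below `tol` or `max_iter` is reached. With
#' probability `c` the walker moves (splitting between 1-hop and 2-hop
#' moves by the node-wise \eqn{\alpha} fractions); with probability `1 - c`
#' it restarts at the start node. In per-node mode the mixing applies
#' row-wise to `P` and `P^2` before transposition, so each combined row
#' stays stochastic and probability mass is conserved exactly.
#'
#' @param model a [transition_model()].
#' @param start start node: label or 1-based index.
#' @param c continuation probability in `[0, 1)`; `1 - c` is the restart
#'   probability. Default 0.85, the common restart-walk convention.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; hitting it yields a warning carrying the
#'   final residual.
#' @return A list of class `rwr_trace`: `r` (named stationary probability
#'   vector), `iterations`, `residual`, `converged`.
#' @seealso [rwr_closed_form()] for the exact linear-solve solution.
#' @export
rwr_iterate <- function(model, start, c = 0.85, tol = 1e-10, max_iter = 1000L) {
  check_walk_args(c, tol, max_iter)
  i <- resolve_start(model, start)
  n <- length(model$labels)
  At <- t(mixed_operator(model))
  r0 <- numeric(n)
  r0[i] <- 1
  restart <- (1 - c) * r0
  r <- r0
  iters <- 0L
  residual <- Inf
  while (iters < max_iter) {
    r_new <- c * (At %*% r) + restart
    r_new <- as.numeric(r_new)
    residual <- sum(abs(r_new - r))
    r <- r_new
    iters <- iters + 1L
    if (residual < tol) break
  }
  converged <- residual < tol
  if (!converged) {
    warn(sprintf(
      "2hopRWR did not converge in %d iterations (final L1 residual %.3g).",
      max_iter, residual
    ))
  }
  structure(
    list(
      r = setNames(r, model$labels), iterations = iters,
      residual = residual, converged = converged
    ),
    class = "rwr_trace"
  )
}

#' Closed-form stationary distribution of the 2-hop walk
#'
#' The iteration is an affine contraction with fixed point
#' \deqn{r_\infty = (1 - c)\,\bigl(I - c(\alpha_1 P^\top + \alpha_2 (P^2)^\top)\bigr)^{-1} r_0,}
#' the limit guaranteed by the spectral radius of the mixed operator being
#' at most 1 (each row is stochastic), so \eqn{I - cA} is invertible for
#' every `c < 1`. Solved directly; used as the exact oracle for
#' [rwr_iterate()].
#'
#' @inheritParams rwr_iterate
#' @return Named stationary probability vector.
#' @export
rwr_closed_form <- function(model, start, c = 0.85) {
  check_walk_args(c)
  i <- resolve_start(model, start)
  n <- length(model$labels)
  At <- t(mixed_operator(model))
  r0 <- numeric(n)
  r0[i] <- 1
  r <- tryCatch(
    solve(diag(n) - c * At, (1 - c) * r0),
    error = function(e) {
      abort(sprintf("linear system is singular (should not occur for c < 1): %s",
                    conditionMessage(e)))
    }
  )
  setNames(as.numeric(r), model$labels)
}

#' Steady-state probability matrix of the 2-hop walk
#'
#' Row \eqn{i} of \eqn{\Pi = \{\pi_{ij}\}} is the stationary distribution
#' of the walk restarted at node \eqn{v_i}; \eqn{\pi_{ij}} is the
#' probability of finding the walker at \eqn{v_j} once the process started
#' at \eqn{v_i} is stable. Computed in one matrix solve:
#' \eqn{\Pi = (1 - c)(I - cA)^{-1}} with \eqn{A} the row-stochastic mixed
#' operator, so every row sums to 1.
#'
#' @inheritParams rwr_iterate
#' @return An `n x n` matrix of class `steady_state_matrix` with node
#'   labels as dimnames.
#' @export
steady_state <- function(model, c = 0.85) {
  check_walk_args(c)
  n <- length(model$labels)
  A <- mixed_operator(model)
  Pi <- tryCatch(
    (1 - c) * solve(diag(n) - c * A),
    error = function(e) {
      abort(sprintf("linear system is singular (should not occur for c < 1): %s",
                    conditionMessage(e)))
    }
  )
  dimnames(Pi) <- list(model$labels, model$labels)
  class(Pi) <- c("steady_state_matrix", class(Pi))
  Pi
}

#' 2hop-connectivity node scores from the steady-state matrix
#'
#' The default `column_sum` mode scores node \eqn{v_i} by
#' \eqn{S_{2hop}(v_i) = \sum_j \pi_{ji}}: the total stationary mass node
#' \eqn{v_i} receives across walks restarted at every node — the standard
#' restart-walk relevance aggregate; the larger the score, the more
#' important the node. The `row_sum` mode sums row \eqn{i} instead; since
#' each row of \eqn{\Pi} is a probability vector, that score is
#' identically 1 for every node and cannot rank them — it is retained to
#' document the degeneracy, not for use. In both modes the scores total
#' \eqn{n} exactly.
#'
#' @param Pi a [steady_state()] matrix.
#' @param mode `"column_sum"` (default) or `"row_sum"`.
#' @return A tibble with columns `node` and `s_2hop`.
#' @export
s2hop_scores <- function(Pi, mode = c("column_sum", "row_sum")) {
  mode <- match.arg(mode)
  s <- if (mode == "column_sum") colSums(Pi) else rowSums(Pi)
  tibble(node = rownames(Pi), s_2hop = as.numeric(s))
}
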