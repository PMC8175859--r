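# Independent brute-force oracles used to validate the package's
# implementations on small graphs. Deliberately different algorithms from
# the implementation paths (matrix powers and exhaustive subset
# enumeration, not Brandes / Bron-Kerbosch / BFS trees).

# Shortest-path lengths and geodesic counts from adjacency-matrix powers:
# the number of length-L walks between s and t is (A^L)[s,t]; the first L
# with a nonzero count is the distance, and minimal-length walks are
# exactly the geodesics.
oracle_dist_sigma <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  S <- matrix(0, n, n)
  diag(S) <- 1
  Ak <- diag(n)
  if (n >= 2) {
    for (L in 1:(n - 1)) {
      Ak <- Ak %*% A
      newly <- is.infinite(D) & Ak > 0
      D[newly] <- L
      S[newly] <- Ak[newly]
    }
  }
  list(D = D, S = S)
}

# Betweenness over unordered pairs {s,t}, s != t, i not an endpoint:
# geodesics through i counted by the distance decomposition
# d(s,i) + d(i,t) == d(s,t).
oracle_betweenness <- function(A) {
  ds <- oracle_dist_sigma(A)
  D <- ds$D
  S <- ds$S
  n <- nrow(A)
  cb <- numeric(n)
  if (n < 3) return(cb)
  for (i in 1:n) {
    for (s in 1:(n - 1)) {
      for (t in (s + 1):n) {
        if (s == i || t == i || is.infinite(D[s, t])) next
        if (is.finite(D[s, i]) && is.finite(D[i, t]) &&
          D[s, i] + D[i, t] == D[s, t]) {
          cb[i] <- cb[i] + S[s, i] * S[i, t] / S[s, t]
        }
      }
    }
  }
  cb
}

# All simple paths between two nodes by depth-first extension; geodesics
# are the minimal-length ones. Used on tiny graphs to validate the
# matrix-power oracle itself.
oracle_sigma_dfs <- function(A, s, t) {
  n <- nrow(A)
  best <- Inf
  count <- 0
  recurse <- function(v, visited, len) {
    if (len > best) return()
    if (v == t) {
      if (len < best) {
        best <<- len
        count <<- 1
      } else if (len == best) {
        count <<- count + 1
      }
      return()
    }
    for (u in which(A[v, ] > 0)) {
      if (!visited[u]) {
        visited[u] <- TRUE
        recurse(u, visited, len + 1)
        visited[u] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  recurse(s, visited, 0)
  list(dist = best, sigma = count)
}

oracle_closeness <- function(A) {
  D <- oracle_dist_sigma(A)$D
  n <- nrow(A)
  vapply(1:n, function(i) {
    d <- D[i, -i]
    r <- sum(is.finite(d))
    if (r == 0) return(0)
    (r / sum(d[is.finite(d)])) * (r / (n - 1))
  }, numeric(1))
}

# Maximal cliques by exhaustive enumeration of all vertex subsets.
oracle_clique_counts <- function(A) {
  n <- nrow(A)
  counts <- numeric(n)
  for (code in 1:(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(0:(n - 1))) > 0)
    k <- length(members)
    sub <- A[members, members, drop = FALSE]
    if (k > 1 && any(sub[upper.tri(sub)] == 0)) next # not complete
    outside <- setdiff(1:n, members)
    maximal <- length(outside) == 0 ||
      !any(vapply(outside, function(u) all(A[u, members] > 0), logical(1)))
    if (maximal) counts[members] <- counts[members] + 1
  }
  counts
}

# Exact-distance-2 alpha fractions by explicit two-step reachability.
oracle_alpha1 <- function(A) {
  n <- nrow(A)
  vapply(1:n, function(i) {
    n1 <- which(A[i, ] > 0)
    n2 <- setdiff(which(colSums(A[n1, , drop = FALSE] > 0) > 0), c(i, n1))
    if (length(n1) + length(n2) == 0) 1 else length(n1) / (length(n1) + length(n2))
  }, numeric(1))
}

# Classical restart walk solved directly (the 1-hop reduction target).
oracle_classical_rwr <- function(W, start, c) {
  n <- nrow(W)
  d <- rowSums(W)
  P <- W / ifelse(d > 0, d, 1)
  for (i in which(d == 0)) P[i, i] <- 1
  r0 <- numeric(n)
  r0[start] <- 1
  as.numeric(solve(diag(n) - c * t(P), (1 - c) * r0))
}

# Brute-force maximizer of cor(X a, Y b) for 2-column blocks: coarse angle
# grid plus Nelder-Mead refinement.
oracle_cca_rho <- function(X, Y) {
  X <- scale(as.matrix(X), scale = FALSE)
  Y <- scale(as.matrix(Y), scale = FALSE)
  obj <- function(par) {
    a <- c(cos(par[1]), sin(par[1]))
    b <- c(cos(par[2]), sin(par[2]))
    -abs(cor(X %*% a, Y %*% b))
  }
  grid <- as.matrix(expand.grid(
    th = seq(0, pi, length.out = 60),
    ph = seq(0, pi, length.out = 60)
  ))
  vals <- apply(grid, 1, obj)
  best <- grid[which.min(vals), ]
  refined <- stats::optim(best, obj,
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 5000)
  )
  -refined$value
}

# Random symmetric integer-weight test graph (possibly disconnected).
rand_graph <- function(n, p = 0.4, max_w = 9) {
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  edges <- stats::runif(sum(up)) < p
  W[up][edges] <- sample.int(max_w, sum(edges), replace = TRUE)
  W <- W + t(W)
  weighted_graph(W)
}

# Random connected weighted graph (resampled until connected).
rand_connected_graph <- function(n, p = 0.3, max_w = 9) {
  repeat {
    g <- rand_graph(n, p, max_w)
    comp <- oracle_dist_sigma((g$W > 0) * 1)$D
    if (all(is.finite(comp))) return(g)
  }
}
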