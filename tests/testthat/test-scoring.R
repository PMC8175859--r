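toy_table <- function(M) {
  # wrap a 5-column normalized matrix as a feature_table for gfs_score
  tab <- tibble::tibble(node = paste0("R", seq_len(nrow(M))))
  raw <- c("c_d", "c_b", "c_c", "n_mc", "s_2hop")
  for (j in 1:5) tab[[raw[j]]] <- M[, j]
  for (j in 1:5) tab[[paste0("n", raw[j])]] <- M[, j]
  class(tab) <- c("feature_table", class(tab))
  tab
}

test_that("min-max normalization rescales, flags constants, is idempotent", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- normalize_minmax(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
  # floating-point-constant vectors are treated as constant, not amplified
  expect_warning(z2 <- normalize_minmax(1 + c(0, 1e-15, -1e-15)), "constant")
  expect_equal(z2, c(0, 0, 0))
  v <- normalize_minmax(stats::rnorm(10))
  expect_equal(normalize_minmax(v), v)
  expect_error(normalize_minmax(c(1, Inf)), "finite")
})

test_that("feature table columns agree with the stand-alone operations", {
  withr::local_seed(19)
  g <- rand_connected_graph(8, 0.4)
  ft <- suppressWarnings(node_features(g, c = 0.85))
  expect_s3_class(ft, "feature_table")
  expect_equal(ft$c_d, degree_centrality(g)$c_d)
  expect_equal(ft$c_b, betweenness_centrality(g)$c_b)
  expect_equal(ft$c_c, closeness_centrality(g)$c_c)
  expect_equal(ft$n_mc, maximal_clique_counts(g)$n_mc)
  Pi <- steady_state(transition_model(g), c = 0.85)
  expect_equal(ft$s_2hop, s2hop_scores(Pi)$s_2hop)
  expect_equal(ft$nc_d, normalize_minmax(ft$c_d))
  expect_true(all(as.matrix(ft[, c("nc_d", "nc_b", "nc_c", "nn_mc", "ns_2hop")]) >= 0))
  expect_true(all(as.matrix(ft[, c("nc_d", "nc_b", "nc_c", "nn_mc", "ns_2hop")]) <= 1))
})

test_that("fully symmetric graphs normalize to all-zero features", {
  K3 <- weighted_graph(matrix(1, 3, 3) - diag(3))
  expect_warning(ft <- node_features(K3), "constant")
  expect_equal(as.matrix(ft[, c("nc_d", "nc_b", "nc_c", "nn_mc", "ns_2hop")]),
    matrix(0, 3, 5),
    ignore_attr = TRUE
  )
})

test_that("GFS is the stated convex combination with validated weights", {
  M <- rbind(c(1, 1, 1, 1, 1), c(1, 0, 0, 0, 0), c(0, 0, 0, 0, 0))
  tab <- toy_table(M)
  expect_equal(gfs_score(tab)$gfs, c(1, 0.2, 0))
  expect_equal(gfs_score(tab, c(1, 0, 0, 0, 0))$gfs, M[, 1])
  # unnormalized weights are rescaled to sum 1
  expect_equal(gfs_score(tab, rep(2, 5))$gfs, gfs_score(tab)$gfs)
  expect_error(gfs_score(tab, rep(1 / 4, 4)), "5 weights")
  expect_error(gfs_score(tab, c(-1, 1, 1, 1, 1)), "nonnegative")
})

test_that("GFS is monotone in each normalized feature", {
  withr::local_seed(23)
  M <- matrix(stats::runif(40), 8, 5)
  w <- c(0.3, 0.1, 0.2, 0.25, 0.15)
  base <- gfs_score(toy_table(M), w)$gfs
  for (j in 1:5) {
    M2 <- M
    M2[3, j] <- min(1, M2[3, j] + 0.2)
    bumped <- gfs_score(toy_table(M2), w)$gfs
    expect_gte(bumped[3], base[3])
  }
})

test_that("weight fitting recovers planted feature combinations", {
  withr::local_seed(41)
  M <- matrix(stats::runif(100), 20, 5)
  tab <- toy_table(M)
  w1 <- fit_gfs_weights(tab, M[, 1])
  expect_equal(unname(w1), c(1, 0, 0, 0, 0), tolerance = 1e-8)
  w13 <- fit_gfs_weights(tab, 0.5 * M[, 1] + 0.5 * M[, 3])
  expect_equal(unname(w13), c(0.5, 0, 0.5, 0, 0), tolerance = 1e-8)
  expect_equal(sum(w13), 1)
  expect_error(fit_gfs_weights(tab, 1:3), "one value per node")
  expect_error(fit_gfs_weights(tab[1:3, ], 1:3), "at least 6")
})

test_that("weight fitting survives pure-noise scores without crashing", {
  withr::local_seed(43)
  M <- matrix(stats::runif(500), 100, 5)
  w <- fit_gfs_weights(toy_table(M), stats::rnorm(100, mean = 10))
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))
})

test_that("differential ranking sorts descending with stable label ties", {
  ga <- tibble::tibble(node = c("a", "b", "c"), gfs = c(0.1, 0.5, 0.3))
  gb <- tibble::tibble(node = c("a", "b", "c"), gfs = c(0, 0, 0))
  r <- differential_ranking(ga, gb, top_k = 2)
  expect_identical(r$node, c("b", "c", "a"))
  expect_equal(r$rank, 1:3)
  expect_identical(r$top, c(TRUE, TRUE, FALSE))

  same <- differential_ranking(ga, ga, top_k = 1)
  expect_equal(same$delta, rep(0, 3))
  expect_identical(same$node, c("a", "b", "c")) # label order breaks ties

  gb2 <- tibble::tibble(node = c("a", "b", "x"), gfs = c(0, 0, 0))
  expect_error(differential_ranking(ga, gb2), class = "gfsnet_error_labels")
})

test_that("swapping groups negates deltas and reverses the order", {
  withr::local_seed(47)
  ga <- tibble::tibble(node = paste0("R", 1:9), gfs = stats::runif(9))
  gb <- tibble::tibble(node = paste0("R", 1:9), gfs = stats::runif(9))
  fwd <- differential_ranking(ga, gb, top_k = 3)
  rev <- differential_ranking(gb, ga, top_k = 3)
  expect_equal(
    rev$delta[match(fwd$node, rev$node)],
    -fwd$delta
  )
  expect_identical(rev$node, rev(fwd$node))
})

test_that("first canonical correlation handles exact and degenerate cases", {
  withr::local_seed(53)
  x <- matrix(stats::rnorm(30), 30, 1)
  res <- cca_first(x, 2 * x + 7)
  expect_equal(res$rho, 1, tolerance = 1e-10)
  expect_s3_class(glance(res), "tbl_df")
  expect_equal(glance(res)$rho, res$rho)
  expect_equal(nrow(tidy(res)), 2)

  # single varying pair reduces to plain Pearson |r|
  y <- matrix(stats::rnorm(30), 30, 1)
  expect_equal(cca_first(x, y)$rho, abs(cor(x, y)[1, 1]), tolerance = 1e-10)

  const <- cbind(y, 5)
  expect_warning(res2 <- cca_first(x, const), "zero-variance")
  expect_equal(res2$rho, abs(cor(x, y)[1, 1]), tolerance = 1e-10)

  expect_error(cca_first(x[1:2, , drop = FALSE], y[1:2, , drop = FALSE]), "at least 3")
  expect_error(cca_first(x, y[1:10, , drop = FALSE]), "same number")
})

test_that("rho matches a brute-force correlation maximizer on 2x2 blocks", {
  withr::local_seed(59)
  for (rep in 1:5) {
    X <- matrix(stats::rnorm(400), 200, 2)
    Y <- 0.5 * X %*% matrix(stats::rnorm(4), 2) + matrix(stats::rnorm(400), 200, 2)
    expect_equal(cca_first(X, Y)$rho, oracle_cca_rho(X, Y), tolerance = 1e-6)
  }
})

test_that("rho is invariant under invertible affine transforms of each block", {
  withr::local_seed(61)
  X <- matrix(stats::rnorm(300), 100, 3)
  Y <- matrix(stats::rnorm(200), 100, 2)
  base <- cca_first(X, Y)$rho
  A <- matrix(stats::rnorm(9), 3)
  while (abs(det(A)) < 0.1) A <- matrix(stats::rnorm(9), 3)
  B <- matrix(c(2, 1, 0, 3), 2)
  rho2 <- cca_first(
    sweep(X %*% A, 2, c(1, -2, 3), "+"),
    sweep(Y %*% B, 2, c(10, 20), "+")
  )$rho
  expect_equal(rho2, base, tolerance = 1e-8)
})
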