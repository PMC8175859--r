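#' Specification for a synthetic two-group connectome study
#'
#' Describes a pair of subject groups sharing one Erdős–Rényi-style base
#' topology with integer fiber-count weights, where a designated node
#' subset has all incident edge weights attenuated in the case group — a
#' planted structural deficit the downstream ranking should recover.
#' Defaults emulate an AAL-90-scale study: 90 regions, 15% edge density,
#' median fiber count 30 on present connections, 10 subjects per group,
#' 5 affected nodes at attenuation 0.2, 20% between-subject noise.
#'
#' @param n_nodes number of regions.
#' @param edge_density fraction of node pairs connected, in `(0, 1]`.
#' @param weight_scale median fiber count of a present connection.
#' @param n_subjects subjects per group.
#' @param affected_nodes indices of planted affected nodes (default: the
#'   first 5).
#' @param attenuation multiplier in `[0, 1]` applied to every edge incident
#'   to an affected node in the case group (1 = null, no effect).
#' @param subject_noise_cv coefficient of variation of the multiplicative
#'   log-normal per-edge subject noise.
#' @param seed integer RNG seed; every generated artifact is a
#'   deterministic function of the spec.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 90, edge_density = 0.15, weight_scale = 30,
                           n_subjects = 10, affected_nodes = 1:5,
                           attenuation = 0.2, subject_noise_cv = 0.2,
                           seed = 1L) {
  if (n_nodes < 3) abort("`n_nodes` must be at least 3.")
  if (edge_density <= 0 || edge_density > 1) abort("`edge_density` must be in (0, 1].")
  if (weight_scale <= 0) abort("`weight_scale` must be positive.")
  if (attenuation < 0 || attenuation > 1) abort("`attenuation` must be in [0, 1].")
  if (subject_noise_cv < 0) abort("`subject_noise_cv` must be nonnegative.")
  affected_nodes <- as.integer(affected_nodes)
  if (length(affected_nodes) > 0 &&
    (min(affected_nodes) < 1 || max(affected_nodes) > n_nodes)) {
    abort("`affected_nodes` must be indices in 1..n_nodes.")
  }
  structure(
    list(
      n_nodes = as.integer(n_nodes), edge_density = edge_density,
      weight_scale = weight_scale, n_subjects = as.integer(n_subjects),
      affected_nodes = affected_nodes, attenuation = attenuation,
      subject_noise_cv = subject_noise_cv, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# sdlog of a log-normal with mean 1 and coefficient of variation cv
lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Generate the shared base network of a synthetic study
#'
#' Samples a symmetric Erdős–Rényi topology at `edge_density`, resampling
#' (up to 50 times) until the skeleton is connected, then assigns each
#' edge an integer fiber count: log-normal with median `weight_scale`,
#' rounded and floored at 1. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return A [weighted_graph()] with labels `R1..Rn`.
#' @export
generate_base_network <- function(spec) {
  withr::with_seed(spec$seed, {
    n <- spec$n_nodes
    A <- NULL
    for (try in 1:50) {
      ig <- igraph::sample_gnp(n, spec$edge_density)
      if (igraph::is_connected(ig)) {
        A <- igraph::as_adjacency_matrix(ig, sparse = FALSE)
        break
      }
    }
    if (is.null(A)) {
      abort("could not sample a connected topology in 50 tries; increase `edge_density`.")
    }
    m <- sum(A[upper.tri(A)])
    w <- pmax(1, round(stats::rlnorm(m,
      meanlog = log(spec$weight_scale),
      sdlog = 0.5
    )))
    W <- matrix(0, n, n)
    W[upper.tri(W)][A[upper.tri(A)] > 0] <- w
    W <- W + t(W)
    weighted_graph(W, labels = paste0("R", seq_len(n)))
  })
}

#' Generate a matched control/case pair of subject groups
#'
#' Both groups share one base topology (so the only systematic group
#' difference is the planted one). Each control subject is the base matrix
#' with i.i.d. multiplicative log-normal per-edge noise (mean 1, CV
#' `subject_noise_cv`), re-rounded to nonnegative integers. Case subjects
#' are built the same way after first scaling every edge incident to an
#' affected node by `attenuation` — the deficit is structural, applied
#' before measurement noise.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `control` and `case`, each a list of
#'   `spec$n_subjects` [weighted_graph()]s, plus `base` and `spec`.
#' @export
make_group_pair <- function(spec) {
  base <- generate_base_network(spec)
  W0 <- base$W
  Wcase <- W0
  if (length(spec$affected_nodes) > 0) {
    Wcase[spec$affected_nodes, ] <- Wcase[spec$affected_nodes, ] * spec$attenuation
    Wcase[, spec$affected_nodes] <- W0[, spec$affected_nodes] * spec$attenuation
  }
  sdlog <- lnorm_sdlog(spec$subject_noise_cv)
  noisy_subject <- function(W) {
    n <- nrow(W)
    E <- matrix(1, n, n)
    m <- sum(upper.tri(W))
    mult <- if (sdlog > 0) {
      stats::rlnorm(m, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, m)
    }
    E[upper.tri(E)] <- mult
    E[lower.tri(E)] <- t(E)[lower.tri(E)]
    weighted_graph(pmax(round(W * E), 0), labels = base$labels)
  }
  withr::with_seed(spec$seed + 1L, {
    control <- lapply(seq_len(spec$n_subjects), function(i) noisy_subject(W0))
    case <- lapply(seq_len(spec$n_subjects), function(i) noisy_subject(Wcase))
  })
  list(control = control, case = case, base = base, spec = spec)
}

#' Write a synthetic study to per-subject TSV matrices
#'
#' Creates `control/` and `case/` subdirectories of `out_dir` holding one
#' matrix file per subject, plus a `manifest.json` recording the full spec
#' for reproducibility.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return The generated pair, invisibly.
#' @export
simulate_groups <- function(spec, out_dir) {
  pair <- make_group_pair(spec)
  for (grp in c("control", "case")) {
    dir.create(file.path(out_dir, grp), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(pair[[grp]])) {
      write_weight_matrix(
        pair[[grp]][[i]],
        file.path(out_dir, grp, sprintf("subject_%02d.tsv", i))
      )
    }
  }
  jsonlite::write_json(unclass(spec), file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE
  )
  invisible(pair)
}
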