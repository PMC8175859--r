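#' Read a directory of subject matrices as a group
#'
#' Reads every `*.tsv` / `*.csv` / `*.txt` file in a directory (sorted by
#' name) with [read_weight_matrix()] and cleans each subject with
#' [clean_graph()].
#'
#' @param dir directory of matrix files.
#' @param min_weight per-subject denoising threshold (see [clean_graph()]).
#' @param labels_path optional shared label file.
#' @return A list of [weighted_graph()]s.
#' @export
read_group <- function(dir, min_weight = 1, labels_path = NULL) {
  if (!dir.exists(dir)) {
    abort(sprintf("group directory not found: %s", dir), class = "gfsnet_error_io")
  }
  files <- sort(list.files(dir, pattern = "\\.(tsv|csv|txt)$", full.names = TRUE))
  if (length(files) == 0) {
    abort(sprintf("no matrix files in %s", dir), class = "gfsnet_error_io")
  }
  lapply(files, function(f) {
    clean_graph(read_weight_matrix(f, labels_path = labels_path),
      min_weight = min_weight
    )
  })
}

#' Compare two groups of networks by GFS difference
#'
#' The full differential workflow: clean and average each group, compute
#' the five-feature table and GFS of each group-average network, and rank
#' nodes by `GFS_a - GFS_b`. Subjects are thresholded before averaging;
#' the averaged matrix is not re-thresholded.
#'
#' @param group_a,group_b lists of [weighted_graph()]s (e.g., control and
#'   case). Scalars of the walk apply to both groups identically.
#' @param min_weight per-subject denoising threshold.
#' @param weights GFS feature weights (see [gfs_score()]).
#' @param top_k how many top-ranked nodes to flag.
#' @inheritParams node_features
#' @return A list of class `group_comparison`: `ranking`
#'   (a [differential_ranking()]), `features_a`, `features_b`, `gfs_a`,
#'   `gfs_b`, `avg_a`, `avg_b`.
#' @export
compare_groups <- function(group_a, group_b, min_weight = 1,
                           c = 0.85, alpha_mode = c("per_node", "scalar"),
                           scalar_alpha1 = NULL, weighted_paths = FALSE,
                           weights = rep(1 / 5, 5), top_k = 10) {
  alpha_mode <- match.arg(alpha_mode)
  clean_members <- function(grp) {
    lapply(grp, clean_graph, min_weight = min_weight)
  }
  avg_a <- clean_graph(average_group(clean_members(group_a)), min_weight = 0)
  avg_b <- clean_graph(average_group(clean_members(group_b)), min_weight = 0)
  if (!identical(avg_a$labels, avg_b$labels)) {
    abort("the two groups have different node labels.", class = "gfsnet_error_labels")
  }
  fa <- suppressWarnings(node_features(avg_a,
    c = c, alpha_mode = alpha_mode,
    scalar_alpha1 = scalar_alpha1, weighted_paths = weighted_paths
  ))
  fb <- suppressWarnings(node_features(avg_b,
    c = c, alpha_mode = alpha_mode,
    scalar_alpha1 = scalar_alpha1, weighted_paths = weighted_paths
  ))
  ga <- gfs_score(fa, weights)
  gb <- gfs_score(fb, weights)
  structure(
    list(
      ranking = differential_ranking(ga, gb, top_k = top_k),
      features_a = fa, features_b = fb,
      gfs_a = ga, gfs_b = gb,
      avg_a = avg_a, avg_b = avg_b,
      params = list(
        min_weight = min_weight, c = c, alpha_mode = alpha_mode,
        scalar_alpha1 = scalar_alpha1, weighted_paths = weighted_paths,
        weights = check_gfs_weights(weights), top_k = top_k
      )
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %d nodes; top %d nodes by GFS difference:\n",
    nrow(x$ranking), sum(x$ranking$top)
  ))
  print(as_tibble(x$ranking[x$ranking$top, c("node", "delta", "rank")]))
  invisible(x)
}

#' Run the group comparison from directories and write artifacts
#'
#' Reads both groups, runs [compare_groups()], and writes `features.tsv`
#' (both groups, long), `gfs.tsv`, `delta_ranking.tsv`, and
#' `manifest.json` (all parameters, input file hashes, package version)
#' into `out_dir`.
#'
#' @param group_a_dir,group_b_dir directories of subject matrices.
#' @param out_dir output directory (created if needed).
#' @param labels_path optional shared label file.
#' @inheritParams compare_groups
#' @return The `group_comparison`, invisibly.
#' @export
run_compare <- function(group_a_dir, group_b_dir, out_dir,
                        labels_path = NULL, min_weight = 1, c = 0.85,
                        alpha_mode = c("per_node", "scalar"),
                        scalar_alpha1 = NULL, weighted_paths = FALSE,
                        weights = rep(1 / 5, 5), top_k = 10) {
  alpha_mode <- match.arg(alpha_mode)
  ga <- read_group(group_a_dir, min_weight = min_weight, labels_path = labels_path)
  gb <- read_group(group_b_dir, min_weight = min_weight, labels_path = labels_path)
  cmp <- compare_groups(ga, gb,
    min_weight = min_weight, c = c, alpha_mode = alpha_mode,
    scalar_alpha1 = scalar_alpha1, weighted_paths = weighted_paths,
    weights = weights, top_k = top_k
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(cmp$features_a), group = "a", .before = 1),
    dplyr::mutate(as_tibble(cmp$features_b), group = "b", .before = 1)
  )
  write_table(feats, file.path(out_dir, "features.tsv"))
  gfs_tab <- tibble(
    node = cmp$gfs_a$node, gfs_a = cmp$gfs_a$gfs, gfs_b = cmp$gfs_b$gfs
  )
  write_table(gfs_tab, file.path(out_dir, "gfs.tsv"))
  write_table(as_tibble(cmp$ranking), file.path(out_dir, "delta_ranking.tsv"))
  hash_dir <- function(d) {
    fs <- sort(list.files(d, pattern = "\\.(tsv|csv|txt)$", full.names = TRUE))
    setNames(
      vapply(fs, function(f) {
        unname(rlang::hash(paste(readLines(f), collapse = "\n")))
      }, character(1)),
      basename(fs)
    )
  }
  manifest <- list(
    package = "gfsnet",
    version = as.character(utils::packageVersion("gfsnet")),
    params = cmp$params,
    inputs = list(
      group_a = list(dir = group_a_dir, files = as.list(hash_dir(group_a_dir))),
      group_b = list(dir = group_b_dir, files = as.list(hash_dir(group_b_dir)))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(cmp)
}

#' Run canonical correlation from two observation tables on disk
#'
#' Reads two delimited tables (one row per observation), computes the
#' first canonical pair with [cca_first()], and writes `cca.tsv`
#' (rho plus loadings) into `out_dir`.
#'
#' @param x_path,y_path TSV/CSV tables with a header row.
#' @param out_dir output directory (created if needed).
#' @return The [cca_first()] result, invisibly.
#' @export
run_cca <- function(x_path, y_path, out_dir) {
  read_block <- function(p) {
    first <- readLines(p, n = 1L)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
    utils::read.delim(p, sep = sep, check.names = FALSE)
  }
  X <- read_block(x_path)
  Y <- read_block(y_path)
  res <- cca_first(X, Y)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- dplyr::bind_rows(
    tibble(block = "rho", term = "rho", value = res$rho),
    dplyr::rename(tidy(res), value = "loading")
  )
  write_table(out, file.path(out_dir, "cca.tsv"))
  invisible(res)
}
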