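#' Construct a weighted, undirected, node-labelled network
#'
#' A `weighted_graph` holds a square, symmetric, nonnegative weight matrix
#' `W` (for structural connectomes: the fiber-number matrix, one row/column
#' per brain region) together with an ordered vector of node labels. The
#' diagonal is required to be zero: edges connect distinct regions only.
#'
#' @param W square numeric matrix of nonnegative edge weights.
#' @param labels character vector of unique node labels, one per row of `W`.
#'   Defaults to dimnames of `W`, or `R1..Rn` when absent.
#' @return An object of class `weighted_graph`: a list with elements
#'   `labels` and `W` (with labels as dimnames).
#' @examples
#' weighted_graph(matrix(c(0, 5, 5, 0), 2))
#' @export
weighted_graph <- function(W, labels = NULL) {
  if (!is.matrix(W) || !is.numeric(W)) {
    abort("`W` must be a numeric matrix.", class = "gfsnet_error_matrix")
  }
  if (nrow(W) != ncol(W)) {
    abort(
      sprintf("non-square matrix: %d rows but %d columns.", nrow(W), ncol(W)),
      class = "gfsnet_error_nonsquare"
    )
  }
  if (is.null(labels)) {
    labels <- rownames(W) %||% paste0("R", seq_len(nrow(W)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(W)) {
    abort(
      sprintf(
        "label count mismatch: %d labels for a %d-node matrix.",
        length(labels), nrow(W)
      ),
      class = "gfsnet_error_labels"
    )
  }
  if (anyDuplicated(labels)) {
    abort("node labels must be unique.", class = "gfsnet_error_labels")
  }
  bad <- which(is.na(W), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(
      sprintf("NaN/NA entry at row %d, column %d.", bad[1, 1], bad[1, 2]),
      class = "gfsnet_error_nan"
    )
  }
  bad <- which(W < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(
      sprintf("negative entry at row %d, column %d.", bad[1, 1], bad[1, 2]),
      class = "gfsnet_error_negative"
    )
  }
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-8, check.attributes = FALSE))) {
    abort("matrix is not symmetric; use clean_graph() to symmetrize near-symmetric input.",
      class = "gfsnet_error_asymmetric"
    )
  }
  if (any(diag(W) != 0)) {
    abort("diagonal must be zero (self-loops are not modelled); use clean_graph().",
      class = "gfsnet_error_diagonal"
    )
  }
  dimnames(W) <- list(labels, labels)
  structure(list(labels = labels, W = W), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  n_edges <- sum(x$W[upper.tri(x$W)] > 0)
  cat(sprintf(
    "<weighted_graph> %d nodes, %d edges, total weight %g\n",
    length(x$labels), n_edges, sum(x$W) / 2
  ))
  invisible(x)
}

n_nodes <- function(g) length(g$labels)

#' Read a weight matrix from a delimited text file
#'
#' Reads a square numeric matrix in TSV or CSV form (delimiter sniffed from
#' the first line; whitespace- or comma-delimited). An optional header row
#' and/or first label column is detected and used for node labels; a
#' separate label file (one label per line) overrides both.
#'
#' @param path path to the matrix file.
#' @param labels_path optional path to a plain-text label file.
#' @return A [weighted_graph()].
#' @export
read_weight_matrix <- function(path, labels_path = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path), class = "gfsnet_error_io")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  raw <- utils::read.table(path,
    header = FALSE, sep = sep, stringsAsFactors = FALSE,
    colClasses = NA, check.names = FALSE, comment.char = ""
  )
  labels <- NULL
  # header row present when the first row is non-numeric
  first_row_num <- suppressWarnings(as.numeric(unlist(raw[1, ])))
  if (anyNA(first_row_num)) {
    labels <- as.character(unlist(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
  }
  # label column present when the first column is non-numeric
  first_col_num <- suppressWarnings(as.numeric(raw[[1]]))
  if (anyNA(first_col_num)) {
    col_labels <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
    if (is.null(labels)) labels <- col_labels
    if (length(labels) == nrow(raw) + 1) labels <- labels[-1]
  }
  W <- as.matrix(vapply(raw, function(col) {
    x <- suppressWarnings(as.numeric(col))
    if (anyNA(x) && !anyNA(col)) {
      abort("non-numeric entries in matrix body.", class = "gfsnet_error_nan")
    }
    x
  }, numeric(nrow(raw))))
  if (nrow(raw) == 1L) W <- matrix(W, nrow = 1L)
  dimnames(W) <- NULL
  if (!is.null(labels_path)) {
    labels <- readLines(labels_path)
    labels <- labels[nzchar(trimws(labels))]
  }
  weighted_graph(W, labels = labels)
}

#' Threshold, zero the diagonal, and symmetrize a network
#'
#' Edge weights below `min_weight` are set to zero (denoising threshold for
#' spurious low-count fiber connections), the diagonal is zeroed, and a
#' near-symmetric matrix is symmetrized by averaging with its transpose.
#' Asymmetry larger than `symmetrize_tol * max(W)` is an error rather than a
#' silent fix.
#'
#' @param g a [weighted_graph()] or a raw square matrix.
#' @param min_weight nonnegative threshold; entries strictly below it become 0.
#'   Default 1: any traced fiber forms an edge.
#' @param symmetrize_tol relative tolerance for asymmetry, as a fraction of
#'   the largest weight.
#' @return A new [weighted_graph()].
#' @export
clean_graph <- function(g, min_weight = 1, symmetrize_tol = 1e-6) {
  if (min_weight < 0) abort("`min_weight` must be nonnegative.")
  W <- if (inherits(g, "weighted_graph")) g$W else as.matrix(g)
  labels <- if (inherits(g, "weighted_graph")) g$labels else rownames(W)
  if (anyNA(W)) abort("NaN/NA entries in matrix.", class = "gfsnet_error_nan")
  if (any(W < 0)) abort("negative entries in matrix.", class = "gfsnet_error_negative")
  gap <- max(abs(W - t(W)))
  scale <- max(W)
  if (gap > symmetrize_tol * max(scale, .Machine$double.eps)) {
    abort(
      sprintf(
        "asymmetry %g exceeds tolerance %g; refusing to symmetrize.",
        gap, symmetrize_tol * scale
      ),
      class = "gfsnet_error_asymmetric"
    )
  }
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W[W < min_weight] <- 0
  weighted_graph(W, labels = labels)
}

#' Average a group of subject networks element-wise
#'
#' The group-representative network is the element-wise mean of the
#' subjects' weight matrices (e.g., the mean fiber-number matrix of a
#' clinical group). All members must share labels and dimensions.
#'
#' @param group a list of [weighted_graph()] objects with identical labels.
#' @return A [weighted_graph()] holding the mean matrix.
#' @export
average_group <- function(group) {
  if (length(group) == 0) {
    abort("empty group: nothing to average.", class = "gfsnet_error_group")
  }
  if (!all(vapply(group, inherits, logical(1), "weighted_graph"))) {
    abort("all group members must be weighted_graph objects.")
  }
  labels <- group[[1]]$labels
  ok <- vapply(group, function(g) identical(g$labels, labels), logical(1))
  if (!all(ok)) {
    abort(
      sprintf("label mismatch: member %d differs from member 1.", which(!ok)[1]),
      class = "gfsnet_error_group"
    )
  }
  W <- Reduce(`+`, lapply(group, `[[`, "W")) / length(group)
  weighted_graph(W, labels = labels)
}

#' Write a per-node table to TSV
#'
#' Writes a tab-separated file with a header line, one row per node, in the
#' row order of the input (input label order is preserved downstream).
#'
#' @param rows data frame of per-node records.
#' @param path output file path.
#' @return `rows`, invisibly.
#' @export
write_table <- function(rows, path) {
  readr::write_tsv(as_tibble(rows), path)
  invisible(rows)
}

#' Write a weight matrix to TSV
#'
#' Header row and label column are included, so the file round-trips through
#' [read_weight_matrix()].
#'
#' @param g a [weighted_graph()].
#' @param path output file path.
#' @return `g`, invisibly.
#' @export
write_weight_matrix <- function(g, path) {
  df <- as.data.frame(g$W)
  names(df) <- g$labels
  df <- cbind(node = g$labels, df)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(g)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
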