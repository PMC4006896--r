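#' Binary structural network
#'
#' The central container of the pipeline: a symmetric N-by-N 0/1 adjacency
#' matrix with zero diagonal, obtained by binarizing the downscaled
#' connectome at a threshold of one streamline. Streamline counts can be
#' carried along as optional weights (every entry with at least one
#' streamline is a binary connection), and node centroid coordinates can be
#' attached for plotting; neither influences any downstream analysis, which
#' operates on the binary matrix throughout.
#'
#' @param adjacency Symmetric numeric/integer matrix of 0s and 1s with zero
#'   diagonal.
#' @param weights Optional symmetric matrix of non-negative integer
#'   streamline counts; must satisfy `(weights >= 1) == (adjacency == 1)`.
#' @param node_coords Optional N-by-3 matrix of node centroid coordinates
#'   (mm).
#' @return An object of class `binary_network` with elements `n`,
#'   `adjacency`, `weights`, `node_coords`.
#' @seealso [downscale()], [read_adjacency()], [nnz()]
#' @export
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 1
#' net <- binary_network(a)
#' nnz(net) # 2: nonzero entries of the full symmetric matrix
binary_network <- function(adjacency, weights = NULL, node_coords = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stopf("adjacency must be a square matrix")
  n <- nrow(adjacency)
  storage.mode(adjacency) <- "integer"
  if (anyNA(adjacency) || !all(adjacency %in% c(0L, 1L)))
    stopf("adjacency must contain only 0 and 1")
  if (!identical(adjacency, t(adjacency)))
    stopf("adjacency must be symmetric")
  if (any(diag(adjacency) != 0L))
    stopf("adjacency must have a zero diagonal (no self-connections)")
  if (!is.null(weights)) {
    if (!is.matrix(weights) || !all(dim(weights) == n))
      stopf("weights must be an %d x %d matrix", n, n)
    storage.mode(weights) <- "integer"
    if (anyNA(weights) || any(weights < 0L))
      stopf("weights must be non-negative integers")
    if (!identical(weights, t(weights)))
      stopf("weights must be symmetric")
    if (!identical((weights >= 1L) * 1L, adjacency * 1L))
      stopf("weights and adjacency disagree: adjacency[i,j] == 1 iff weights[i,j] >= 1")
  }
  if (!is.null(node_coords)) {
    # NA rows are allowed: nodes whose surface region is empty have no centroid
    if (!is.matrix(node_coords) || ncol(node_coords) != 3L ||
        !is.numeric(node_coords) || nrow(node_coords) != n)
      stopf("node_coords must be a numeric %d x 3 matrix", n)
  }
  dimnames(adjacency) <- NULL
  structure(list(n = n, adjacency = adjacency, weights = weights,
                 node_coords = node_coords),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary_network: %d nodes, %d edges (nnz = %d), density %.4f\n",
              x$n, sum(x$adjacency) / 2L, nnz(x),
              if (x$n > 1) sum(x$adjacency) / (x$n * (x$n - 1)) else 0))
  if (!is.null(x$weights))
    cat(sprintf("  streamline-count weights present (total %d streamlines)\n",
                sum(x$weights) / 2L))
  invisible(x)
}

#' Number of nonzero adjacency entries
#'
#' Counts nonzero entries of the full symmetric adjacency matrix, i.e.
#' twice the undirected edge count — the convention in which connection
#' totals are reported throughout.
#'
#' @param net A [binary_network()].
#' @return Integer scalar.
#' @export
nnz <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  sum(net$adjacency)
}

#' Dense point-to-point connectome
#'
#' Sparse record of which individual surface points are connected by at
#' least one streamline, prior to downscaling to N nodes. Pairs are stored
#' unordered as `i < j` with streamline counts.
#'
#' @param n_points Number of surface points the pair indices refer to.
#' @param pairs Data frame with integer columns `i`, `j` (1-based point
#'   indices, `i < j`) and `count` (streamlines, >= 1).
#' @return An object of class `dense_connectome`.
#' @seealso [build_dense_connectome()], [downscale()]
#' @export
dense_connectome <- function(n_points, pairs) {
  if (!is_count(n_points)) stopf("n_points must be a positive integer")
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) {
    pairs <- data.frame(i = integer(), j = integer(), count = integer())
  } else {
    if (!all(c("i", "j", "count") %in% names(pairs)))
      stopf("pairs must have columns i, j, count")
    pairs <- pairs[, c("i", "j", "count")]
    if (any(pairs$i >= pairs$j))
      stopf("pairs must be stored with i < j")
    if (any(pairs$i < 1L) || any(pairs$j > n_points))
      stopf("pair indices out of range 1..n_points")
    if (any(pairs$count < 1L))
      stopf("pair counts must be >= 1")
    if (anyDuplicated(pairs[, c("i", "j")]))
      stopf("duplicate point pairs in dense connectome")
  }
  rownames(pairs) <- NULL
  structure(list(n_points = as.integer(n_points), pairs = pairs),
            class = "dense_connectome")
}

#' @export
print.dense_connectome <- function(x, ...) {
  cat(sprintf("dense_connectome: %d surface points, %d connected point pairs, %d streamlines\n",
              x$n_points, nrow(x$pairs), sum(x$pairs$count)))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}
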