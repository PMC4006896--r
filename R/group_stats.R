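# Edge-wise two-group comparison on cohorts aligned to a common reference:
# mass-univariate t-tests with FDR control, and the network-based statistic
# (NBS), which assigns permutation-corrected p-values to connected
# components of suprathreshold edges.

# Stack a group's networks into a subjects-by-edges matrix of
# lower-triangle values (binary or weighted).
edge_matrix <- function(group, what = "group") {
  if (is.matrix(group)) return(group)   # already subjects x edges
  if (!is.list(group) || length(group) == 0)
    stopf("%s must be a list of networks or a subjects-by-edges matrix", what)
  rows <- lapply(group, function(s) lower_triangle(net_adj(s)))
  if (length(unique(lengths(rows))) != 1L)
    stopf("%s networks differ in size", what)
  do.call(rbind, rows)
}

# Node pair (i, j), i > j, of each lower-triangle edge index, matching the
# column-major order of lower_triangle().
edge_pairs <- function(n) {
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

# Pooled-variance two-sample t statistic per edge (column), with the
# degenerate zero-variance case mapped to a signed sentinel.
t_sentinel <- 1e12

edge_tstats <- function(x, in_a) {
  xa <- x[in_a, , drop = FALSE]
  xb <- x[!in_a, , drop = FALSE]
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa)
  mb <- colMeans(xb)
  va <- pmax(0, (colSums(xa * xa) - na * ma^2) / (na - 1))
  vb <- pmax(0, (colSums(xb * xb) - nb * mb^2) / (nb - 1))
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  degen <- se == 0
  t[degen] <- sign(ma[degen] - mb[degen]) * t_sentinel
  t
}

#' Edge-wise two-sample t-tests
#'
#' A pooled-variance two-sample t-test contrasting the two groups is
#' computed independently at each of the N(N-1)/2 lower-triangle edges,
#' based on the per-subject connection values (0/1 for binary networks).
#' Networks must have been aligned to a common reference beforehand —
#' edge-wise comparison is only meaningful in a common network space.
#' Edges with zero variance in both groups get t = 0 (equal means, p = 1)
#' or a signed sentinel of magnitude 1e12 (different means, p ~ 0).
#'
#' @param group_a,group_b Lists of [binary_network()]s (>= 2 each, equal
#'   N), or subjects-by-edges numeric matrices of lower-triangle values.
#' @return An object of class `edgewise_test`: `t_stat`, `p_value` (two
#'   sided), `df`, `n_a`, `n_b`, `n_nodes` (NA for matrix input of unknown
#'   N), `edges` (node pair per edge).
#' @export
edgewise_ttest <- function(group_a, group_b) {
  xa <- edge_matrix(group_a, "group_a")
  xb <- edge_matrix(group_b, "group_b")
  if (ncol(xa) != ncol(xb)) stopf("groups differ in edge count")
  if (nrow(xa) < 2L || nrow(xb) < 2L)
    stopf("each group needs at least 2 subjects")
  x <- rbind(xa, xb)
  in_a <- c(rep(TRUE, nrow(xa)), rep(FALSE, nrow(xb)))
  t <- edge_tstats(x, in_a)
  df <- nrow(x) - 2L
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  m <- ncol(x)
  n <- (1 + sqrt(1 + 8 * m)) / 2
  n_nodes <- if (n == round(n)) as.integer(n) else NA_integer_
  structure(list(t_stat = t, p_value = p, df = df,
                 n_a = nrow(xa), n_b = nrow(xb), n_nodes = n_nodes,
                 edges = if (!is.na(n_nodes)) edge_pairs(n_nodes)),
            class = "edgewise_test")
}

#' @export
print.edgewise_test <- function(x, ...) {
  cat(sprintf("edgewise_test: %d edges, groups of %d and %d subjects (df = %d)\n",
              length(x$t_stat), x$n_a, x$n_b, x$df))
  cat(sprintf("  |t| range %.3g .. %.3g; %d edges with p < 0.05 (uncorrected)\n",
              min(abs(x$t_stat)), max(abs(x$t_stat)), sum(x$p_value < 0.05)))
  invisible(x)
}

#' Benjamini-Hochberg FDR discoveries
#'
#' Step-up false discovery rate control at level q over a vector of
#' p-values (the generic correction for the massive multiple-comparison
#' problem of edge-wise testing: N(N-1)/2 tests, e.g. 4465 for N = 95).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q FDR level in (0, 1).
#' @return Logical mask of discoveries.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stopf("q must lie in (0, 1)")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH") <= q
}

# Union-find over the nodes touched by a set of edges; returns, per edge,
# the id of its connected component.
edge_component_ids <- function(pairs) {
  if (nrow(pairs) == 0L) return(integer())
  nodes <- sort(unique(as.vector(pairs)))
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a <- match(pairs[, 1], nodes)
  b <- match(pairs[, 2], nodes)
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(a, find, integer(1))
  match(roots, unique(roots))
}

max_component_edges <- function(pairs) {
  ids <- edge_component_ids(pairs)
  if (length(ids) == 0L) 0L else max(tabulate(ids))
}

#' Network-based statistic (NBS) for two-group comparison
#'
#' The four-step permutation procedure: (1) a two-sample t-test at each
#' edge; (2) thresholding |t| at the primary threshold to form the set of
#' suprathreshold edges; (3) identification of the connected components of
#' that edge set and their sizes; (4) K random relabellings of the subjects
#' into two groups of the original sizes, each yielding the size of its
#' largest suprathreshold component — the empirical null distribution of
#' the maximal component size, from which each observed component gets a
#' corrected p-value `(1 + #(null >= size)) / (K + 1)`. Component size is
#' measured in edges by default (the edge is the unit of inference).
#'
#' The NBS is of no use if the contrast does not form a connected
#' component; with no suprathreshold edges the result is valid but empty.
#' The choice of the primary threshold is left to the caller.
#'
#' @inheritParams edgewise_ttest
#' @param t_threshold Primary threshold on |t| (> 0); an edge is
#'   suprathreshold when |t| exceeds it.
#' @param K Number of permutations (>= 100 recommended).
#' @param seed Integer seed for the permutation engine; the original group
#'   labels are restored after every permutation.
#' @param component_size `"edges"` (default) or `"nodes"`.
#' @return An object of class `nbs_result`: `t_threshold`, `components`
#'   (list of edge-index vectors), `component_edges` (node pairs per
#'   component), `sizes`, `corrected_p`, `null_max_sizes`, `K`.
#' @export
nbs <- function(group_a, group_b, t_threshold, K = 1000L, seed = 1L,
                component_size = c("edges", "nodes")) {
  component_size <- match.arg(component_size)
  if (!is.numeric(t_threshold) || length(t_threshold) != 1L ||
      t_threshold <= 0)
    stopf("t_threshold must be a positive number")
  if (!is_count(K)) stopf("K must be a positive integer")
  xa <- edge_matrix(group_a, "group_a")
  xb <- edge_matrix(group_b, "group_b")
  if (ncol(xa) != ncol(xb)) stopf("groups differ in edge count")
  if (nrow(xa) < 2L || nrow(xb) < 2L)
    stopf("each group needs at least 2 subjects")
  x <- rbind(xa, xb)
  ns <- nrow(x)
  na <- nrow(xa)
  in_a <- c(rep(TRUE, na), rep(FALSE, ns - na))
  m <- ncol(x)
  n_nodes <- (1 + sqrt(1 + 8 * m)) / 2
  if (n_nodes != round(n_nodes))
    stopf("edge count %d is not N(N-1)/2 for integer N", m)
  pairs_all <- edge_pairs(as.integer(n_nodes))

  comp_sizes <- function(supra_idx, max_only) {
    pr <- pairs_all[supra_idx, , drop = FALSE]
    ids <- edge_component_ids(pr)
    if (length(ids) == 0L) return(if (max_only) 0L else list())
    size_of <- function(cid) {
      sel <- ids == cid
      if (component_size == "edges") sum(sel)
      else length(unique(as.vector(pr[sel, , drop = FALSE])))
    }
    sizes <- vapply(seq_len(max(ids)), size_of, numeric(1))
    if (max_only) max(sizes) else list(ids = ids, sizes = sizes)
  }

  t_obs <- edge_tstats(x, in_a)
  supra_obs <- which(abs(t_obs) > t_threshold)
  obs <- comp_sizes(supra_obs, max_only = FALSE)

  null_max <- with_seed(seed, {
    vapply(seq_len(K), function(k) {
      labels_k <- sample(in_a)   # relabel without replacement
      tk <- edge_tstats(x, labels_k)
      comp_sizes(which(abs(tk) > t_threshold), max_only = TRUE)
    }, numeric(1))
  })

  if (is.list(obs) && length(obs)) {
    comps <- lapply(seq_along(obs$sizes),
                    function(cid) supra_obs[obs$ids == cid])
    sizes <- obs$sizes
    pcorr <- vapply(sizes, function(s) (1 + sum(null_max >= s)) / (K + 1),
                    numeric(1))
  } else {
    comps <- list(); sizes <- numeric(); pcorr <- numeric()
  }
  structure(list(t_threshold = t_threshold,
                 components = comps,
                 component_edges = lapply(comps, function(e)
                   pairs_all[e, , drop = FALSE]),
                 sizes = sizes,
                 corrected_p = pcorr,
                 null_max_sizes = null_max,
                 K = as.integer(K),
                 component_size = component_size),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("nbs_result: primary threshold |t| > %g, K = %d permutations\n",
              x$t_threshold, x$K))
  if (length(x$sizes) == 0L) {
    cat("  no suprathreshold components (the contrast forms no connected component)\n")
  } else {
    for (k in seq_along(x$sizes))
      cat(sprintf("  component %d: %d %s, corrected p = %.4g\n",
                  k, x$sizes[k], x$component_size, x$corrected_p[k]))
  }
  invisible(x)
}
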