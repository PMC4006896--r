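# Connected components, the giant component and optimal-N rule, and global
# network metrics normalised against degree-preserving random ensembles.
# Standard graph primitives are delegated to igraph; the Maslov-Sneppen
# randomization (accepted double-edge swaps) is implemented in compiled
# code because its accepted-swap semantics and swap budget are part of the
# method definition.

#' Connected components of a binary network
#'
#' Component ids are contiguous from 1 and deterministic: component 1
#' contains the lowest-indexed node, component 2 the lowest-indexed node
#' not in component 1, and so on.
#'
#' @param net A [binary_network()].
#' @return An object of class `component_decomposition` with
#'   `n_components`, `membership` (per node), `sizes` and `giant_size`.
#' @export
network_components <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  mem <- igraph::components(as_igraph(net))$membership
  mem <- match(mem, unique(mem))   # relabel in first-appearance (node) order
  sizes <- tabulate(mem)
  structure(list(n_components = length(sizes),
                 membership = as.integer(mem),
                 sizes = sizes,
                 giant_size = max(sizes)),
            class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("components: %d (giant component: %d of %d nodes)\n",
              x$n_components, x$giant_size, length(x$membership)))
  invisible(x)
}

#' Restrict a network to its giant component
#'
#' @param net A [binary_network()].
#' @return A [binary_network()] on the largest component's nodes (original
#'   node indices in attribute `nodes`).
#' @export
giant_component <- function(net) {
  comp <- network_components(net)
  keep <- which(comp$membership == which.max(comp$sizes))
  out <- binary_network(net$adjacency[keep, keep, drop = FALSE],
                        weights = if (!is.null(net$weights))
                          net$weights[keep, keep, drop = FALSE],
                        node_coords = if (!is.null(net$node_coords))
                          net$node_coords[keep, , drop = FALSE])
  attr(out, "nodes") <- keep
  out
}

#' Select the optimal number of nodes for a cohort
#'
#' The optimal parcellation is the finest one that still interconnects the
#' whole brain, leaving no nodes isolated: the largest candidate N at which
#' every subject's N-node network forms exactly one connected component
#' spanning all N nodes. Each candidate is evaluated by partitioning the
#' sphere, scaling it to each subject's surface, assigning surface points
#' to nodes and downscaling that subject's dense connectome.
#'
#' @param dense_list List of [dense_connectome()], one per subject.
#' @param surface_list List of [surface_cloud()], same order.
#' @param candidates Strictly increasing positive integers to try (the
#'   reference candidate list is 10, 50, 90, 95, 100, 105, 110, 150, 300,
#'   500, 1000, 3000).
#' @return An object of class `optimal_n`: `optimal_n` (the selected N, or
#'   `NA` if no candidate leaves every subject connected), and `table` (one
#'   row per candidate with per-subject component counts).
#' @export
find_optimal_n <- function(dense_list, surface_list,
                           candidates = default_run_config()$node_counts_to_try) {
  if (length(candidates) == 0 || any(candidates < 1) ||
      is.unsorted(candidates, strictly = TRUE))
    stopf("candidates must be strictly increasing positive integers")
  if (length(dense_list) != length(surface_list) || length(dense_list) == 0)
    stopf("need one dense connectome and one surface per subject")
  ns <- length(dense_list)
  ncomp <- matrix(NA_integer_, length(candidates), ns)
  for (ci in seq_along(candidates)) {
    n <- candidates[ci]
    part <- equal_area_partition(n)
    for (s in seq_len(ns)) {
      refs <- scale_to_surface(part, surface_list[[s]])
      asg <- assign_nodes(surface_list[[s]], refs)
      net <- downscale(dense_list[[s]], asg)
      ncomp[ci, s] <- network_components(net)$n_components
    }
  }
  ok <- apply(ncomp == 1L, 1, all)
  tab <- data.frame(n = candidates, all_connected = ok)
  tab$n_components <- ncomp
  structure(list(optimal_n = if (any(ok)) max(candidates[ok]) else NA_integer_,
                 table = tab),
            class = "optimal_n")
}

#' @export
print.optimal_n <- function(x, ...) {
  if (is.na(x$optimal_n))
    cat("optimal N: none (no candidate leaves every subject connected)\n")
  else
    cat(sprintf("optimal N: %d (finest parcellation with one component in all subjects)\n",
                x$optimal_n))
  print(data.frame(n = x$table$n, all_connected = x$table$all_connected,
                   max_components = apply(x$table$n_components, 1, max)),
        row.names = FALSE)
  invisible(x)
}

#' Degree-preserving randomization of a network
#'
#' Maslov-Sneppen double-edge swaps: repeatedly pick two edges on four
#' distinct nodes and exchange their endpoints, rejecting swaps that would
#' create a duplicate edge. `rewires_per_edge * |E|` accepted swaps are
#' performed (an attempt budget guards inputs such as complete graphs that
#' admit no swap; those come back unchanged). The degree sequence is
#' preserved exactly.
#'
#' @param net A [binary_network()].
#' @param rewires_per_edge Accepted swaps per edge (reference value 1000).
#' @param seed Integer seed (the randomization has its own generator and
#'   does not touch R's RNG state).
#' @return A [binary_network()] with the same degree sequence.
#' @export
rewire_degree_preserving <- function(net, rewires_per_edge = 1000, seed = 1L) {
  stopifnot(inherits(net, "binary_network"))
  m <- sum(net$adjacency) / 2
  binary_network(rewire_ms_cpp(net$adjacency, rewires_per_edge * m,
                               as.integer(seed)))
}

#' Normalised global network metrics
#'
#' Computes the average clustering coefficient C (local clustering over
#' connected triples; nodes of degree < 2 contribute 0), the characteristic
#' path length L (mean shortest path over all unordered node pairs), and
#' the maximised modularity Q (best of `louvain_restarts` seeded Louvain
#' runs). Because these measures depend on the number of edges and the
#' degree distribution, C and L are normalised by their means over an
#' ensemble of `n_random` degree-preserving randomizations
#' ([rewire_degree_preserving()]): `Cr = C / C_rand`, `Lr = L / L_rand`,
#' and the small-world index `swi = Cr / Lr` (> 1 indicates small-world
#' organisation). L of a randomized network that falls apart is measured on
#' its giant component.
#'
#' @param net A connected [binary_network()]; a disconnected network is an
#'   error — restrict to [giant_component()] first if that is what you
#'   mean.
#' @param n_random Size of the random ensemble (reference value 100).
#' @param rewires_per_edge Accepted swaps per edge in each randomization
#'   (reference value 1000).
#' @param seed Integer seed making the ensemble and the Louvain restarts
#'   reproducible.
#' @param louvain_restarts Louvain runs for Q (best modularity kept).
#' @return An object of class `global_metrics`: `C`, `L`, `Q`, `C_rand`,
#'   `L_rand`, `Cr`, `Lr`, `swi`, plus the per-network ensemble values
#'   `C_rand_values`, `L_rand_values` and `n_random`.
#' @export
global_metrics <- function(net, n_random = 100, rewires_per_edge = 1000,
                           seed = 1L, louvain_restarts = 20L) {
  stopifnot(inherits(net, "binary_network"))
  if (!is_count(n_random)) stopf("n_random must be a positive integer")
  comp <- network_components(net)
  if (comp$n_components != 1L)
    stopf(paste("global_metrics() needs a connected network (got %d components);",
                "restrict to giant_component(net) to analyse the largest piece"),
          comp$n_components)
  g <- as_igraph(net)
  cc <- mean_local_clustering(g)
  ll <- igraph::mean_distance(g, directed = FALSE)
  qq <- best_modularity(g, louvain_restarts, seed)

  c_rand <- numeric(n_random)
  l_rand <- numeric(n_random)
  for (k in seq_len(n_random)) {
    rnet <- rewire_degree_preserving(net, rewires_per_edge,
                                     seed = as.integer(seed) + k)
    rg <- as_igraph(rnet)
    c_rand[k] <- mean_local_clustering(rg)
    rcomp <- igraph::components(rg)
    if (rcomp$no > 1L) {
      keep <- which(rcomp$membership == which.max(rcomp$csize))
      rg <- igraph::induced_subgraph(rg, keep)
    }
    l_rand[k] <- igraph::mean_distance(rg, directed = FALSE)
  }
  cr <- cc / mean(c_rand)
  lr <- ll / mean(l_rand)
  structure(list(C = cc, L = ll, Q = qq,
                 C_rand = mean(c_rand), L_rand = mean(l_rand),
                 Cr = cr, Lr = lr, swi = cr / lr,
                 C_rand_values = c_rand, L_rand_values = l_rand,
                 n_random = as.integer(n_random)),
            class = "global_metrics")
}

mean_local_clustering <- function(g) {
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(lc)
}

best_modularity <- function(g, restarts, seed) {
  best <- -Inf
  for (r in seq_len(restarts)) {
    q <- with_seed(as.integer(seed) + 1000L + r,
                   igraph::modularity(igraph::cluster_louvain(g)))
    if (q > best) best <- q
  }
  best
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf("global_metrics (random ensemble: n = %d):\n", x$n_random))
  cat(sprintf("  C  = %.4f   C_rand = %.4f   Cr  = %.4f\n", x$C, x$C_rand, x$Cr))
  cat(sprintf("  L  = %.4f   L_rand = %.4f   Lr  = %.4f\n", x$L, x$L_rand, x$Lr))
  cat(sprintf("  Q  = %.4f   swi = Cr/Lr = %.4f\n", x$Q, x$swi))
  invisible(x)
}
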