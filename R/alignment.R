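# Network-domain alignment: instead of co-registering brains anatomically,
# the nodes of one adjacency matrix are reordered to minimise the absolute
# difference from another. Simulated annealing searches permutation space;
# similarity is the Pearson correlation over the lower triangle.

net_adj <- function(x, what = "network") {
  if (inherits(x, "binary_network")) return(x$adjacency)
  if (is.matrix(x)) return(binary_network(x)$adjacency)
  stopf("%s must be a binary_network or adjacency matrix", what)
}

#' Lower-triangle Pearson correlation of two networks
#'
#' Pearson correlation over the N(N-1)/2 strictly-sub-diagonal adjacency
#' entries (the matrices are symmetric, so only elements under the diagonal
#' are considered: 4950 elements for N = 100, 4465 for N = 95).
#'
#' @param a,b [binary_network()]s (or square 0/1 matrices) with the same N.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_lower_triangle <- function(a, b) {
  ma <- net_adj(a, "a"); mb <- net_adj(b, "b")
  if (nrow(ma) != nrow(mb))
    stopf("networks differ in size (%d vs %d nodes); alignment and comparison require equal N",
          nrow(ma), nrow(mb))
  x <- ma[lower.tri(ma)]
  y <- mb[lower.tri(mb)]
  if (sd(x) == 0 || sd(y) == 0)
    stopf("correlation undefined: a network's lower triangle is constant")
  cor(x, y)
}

alignment_result <- function(reference, moving, perm, cost) {
  ma <- net_adj(reference); mb <- net_adj(moving)
  structure(list(permutation = as.integer(perm),
                 cost = cost,
                 r_before = pearson_lower_triangle(ma, mb),
                 r_after = pearson_lower_triangle(ma, mb[perm, perm]),
                 n = nrow(ma)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d nodes, cost = %g, r %0.4f -> %0.4f, %d nodes moved\n",
              x$n, x$cost, x$r_before, x$r_after,
              sum(x$permutation != seq_len(x$n))))
  invisible(x)
}

#' Align two networks by simulated annealing
#'
#' Reorders the nodes of `moving` to minimise the total absolute difference
#' `sum(abs(reference - moving[p, p]))` over the full matrix. Each restart
#' runs a Metropolis annealing over permutations with transposition
#' proposals, initial temperature `cost0 / ln 2` (a cost-doubling move is
#' accepted with probability 0.5), geometric cooling per sweep of N
#' proposals, and stops after `iterations` sweeps or when the temperature
#' falls below 1e-4 of its initial value. The best cost visited across all
#' restarts wins. The identity permutation is always among the evaluated
#' starts — matrices acquired with similar head positioning are effectively
#' pre-aligned, and for binary matrices a lower cost implies a higher
#' correlation, so `r_after >= r_before` is guaranteed — and one restart
#' starts from the degree-rank matching permutation; remaining restarts
#' start from random permutations.
#'
#' Good solutions are obtainable for matrices up to about 100 nodes; the
#' reference protocol runs 100 restarts and keeps the lowest-cost solution.
#'
#' @param reference Network kept fixed ([binary_network()] or 0/1 matrix).
#' @param moving Network whose nodes are reordered; same N (N >= 2).
#' @param restarts Number of annealing restarts (reference value 100).
#' @param iterations Sweeps per restart; one sweep proposes N swaps.
#' @param cooling Geometric cooling factor per sweep. The default 0.955 is
#'   chosen so the schedule reaches the 1e-4 temperature floor within the
#'   default sweep budget (0.955^200 ~ 1e-4) and the chain actually
#'   freezes; slower cooling needs proportionally more `iterations`.
#' @param seed Integer seed; the search uses its own generator, expanded to
#'   per-restart streams, and is reproducible bit-for-bit.
#' @return An object of class `alignment`: `permutation` (node p of the
#'   aligned matrix is node `permutation[p]` of `moving`), `cost`,
#'   `r_before`, `r_after`, `n`.
#' @seealso [brute_force_align()] for the exhaustive small-N oracle.
#' @export
sa_align <- function(reference, moving, restarts = 100L, iterations = 200L,
                     cooling = 0.955, seed = 1L) {
  ma <- net_adj(reference, "reference"); mb <- net_adj(moving, "moving")
  if (nrow(ma) != nrow(mb))
    stopf("networks differ in size (%d vs %d nodes)", nrow(ma), nrow(mb))
  n <- nrow(ma)
  if (n < 2L) stopf("alignment needs at least 2 nodes")
  if (!is_count(restarts) || !is_count(iterations))
    stopf("restarts and iterations must be positive integers")
  deg_a <- colSums(ma)
  deg_b <- colSums(mb)
  inits <- rbind(seq_len(n),                                      # identity
                 order(deg_b)[rank(deg_a, ties.method = "first")] # degree match
                 ) - 1L
  inits <- inits[seq_len(min(restarts, 2L)), , drop = FALSE]
  res <- sa_align_cpp(ma, mb, inits, as.integer(restarts),
                      as.integer(iterations), cooling, as.integer(seed))
  alignment_result(ma, mb, res$perm + 1L, res$cost)
}

#' Exhaustive alignment over all permutations (small-N oracle)
#'
#' Evaluates the absolute-difference cost for every one of the N!
#' permutations and returns the (lexicographically first) minimum. Only
#' feasible for N <= 9; used as an independent check of [sa_align()].
#'
#' @inheritParams sa_align
#' @return An object of class `alignment`.
#' @export
brute_force_align <- function(reference, moving) {
  ma <- net_adj(reference, "reference"); mb <- net_adj(moving, "moving")
  if (nrow(ma) != nrow(mb)) stopf("networks differ in size")
  res <- exhaustive_align_cpp(ma, mb)
  alignment_result(ma, mb, res$perm + 1L, res$cost)
}

#' Pair-wise alignment of a cohort
#'
#' Aligns every ordered pair of subject networks: entry (i, j) of the
#' correlation matrix is `r_after` when subject j is aligned to subject i
#' as reference (diagonal 1). Alignment is directional, so the matrix need
#' not be symmetric. All permutations are retained so that a sum network
#' can be formed against any chosen reference.
#'
#' @param subjects List of at least 2 [binary_network()]s with equal N.
#' @inheritParams sa_align
#' @return An object of class `group_alignment`: `networks`, `r_matrix`,
#'   `permutations` (list of lists), `cost_matrix`.
#' @export
pairwise_align_group <- function(subjects, restarts = 100L,
                                 iterations = 200L, cooling = 0.955,
                                 seed = 1L) {
  if (!is.list(subjects) || length(subjects) < 2L)
    stopf("a cohort needs at least 2 subject networks")
  ns <- length(subjects)
  nn <- vapply(subjects, function(s) nrow(net_adj(s)), integer(1))
  if (length(unique(nn)) != 1L)
    stopf("all subjects must have the same number of nodes (got %s)",
          paste(unique(nn), collapse = ", "))
  r <- diag(1, ns)
  costs <- matrix(0, ns, ns)
  perms <- replicate(ns, vector("list", ns), simplify = FALSE)
  for (i in seq_len(ns)) {
    perms[[i]][[i]] <- seq_len(nn[1])
    for (j in seq_len(ns)) {
      if (i == j) next
      al <- sa_align(subjects[[i]], subjects[[j]], restarts = restarts,
                     iterations = iterations, cooling = cooling,
                     seed = as.integer(seed) + 1000L * i + j)
      r[i, j] <- al$r_after
      costs[i, j] <- al$cost
      perms[[i]][[j]] <- al$permutation
    }
  }
  structure(list(networks = subjects, r_matrix = r, cost_matrix = costs,
                 permutations = perms),
            class = "group_alignment")
}

#' @export
print.group_alignment <- function(x, ...) {
  ns <- length(x$networks)
  cat(sprintf("group_alignment: %d subjects, %d nodes\n", ns,
              nrow(net_adj(x$networks[[1]]))))
  cat("post-alignment correlation matrix (row = reference):\n")
  print(round(x$r_matrix, 4))
  ref <- select_reference(x)
  cat(sprintf("reference network: subject %d (highest mean correlation)\n", ref))
  invisible(x)
}

#' Choose the cohort's reference network
#'
#' The reference network is the most typical cohort member: the subject
#' whose mean post-alignment correlation with all other subjects (its row
#' of the correlation matrix, excluding the diagonal) is highest. Ties go
#' to the lowest index.
#'
#' @param group A [pairwise_align_group()] result.
#' @return Integer subject index.
#' @export
select_reference <- function(group) {
  stopifnot(inherits(group, "group_alignment"))
  r <- group$r_matrix
  means <- (rowSums(r) - diag(r)) / (ncol(r) - 1)
  which.max(means)   # first maximum = lowest index on ties
}

#' Sum network of an aligned cohort
#'
#' Aligns all subject networks to the reference and adds up the binary
#' connections: entry (a, b) counts the subjects possessing that connection
#' after alignment, creating a template in network space (0 .. S).
#'
#' @param group A [pairwise_align_group()] result.
#' @param reference Reference subject index; defaults to
#'   [select_reference()].
#' @return An object of class `sum_network`: `n`, `counts`, `n_subjects`,
#'   `reference_index`.
#' @export
sum_network <- function(group, reference = select_reference(group)) {
  stopifnot(inherits(group, "group_alignment"))
  ns <- length(group$networks)
  if (!is_count(reference) || reference > ns)
    stopf("reference must be a subject index in 1..%d", ns)
  counts <- net_adj(group$networks[[reference]])
  for (j in seq_len(ns)) {
    if (j == reference) next
    p <- group$permutations[[reference]][[j]]
    adj <- net_adj(group$networks[[j]])
    counts <- counts + adj[p, p]
  }
  structure(list(n = nrow(counts), counts = counts, n_subjects = ns,
                 reference_index = as.integer(reference)),
            class = "sum_network")
}

#' @export
print.sum_network <- function(x, ...) {
  cat(sprintf("sum_network: %d nodes, %d subjects (reference: subject %d)\n",
              x$n, x$n_subjects, x$reference_index))
  tab <- table(factor(x$counts[lower.tri(x$counts)], levels = 0:x$n_subjects))
  cat("connections present in k subjects:\n")
  print(tab)
  invisible(x)
}

#' Rotation-of-parcellation analysis
#'
#' Quantifies the node-discretization error: the reference sphere is
#' rotated about the x, y and z axes (default +/- 10 degrees, which shifts
#' a 95-node parcellation by about half a node), the network is rebuilt
#' from the same dense connectome under each rotated parcellation, global
#' metrics are recomputed, and each rotated network is aligned back to the
#' initial 0-degree network. A coherent streamline bundle that falls on a
#' shifted node border turns one binary connection into two, so the number
#' of binary connections (nnz) changes under rotation. When a rotation
#' disconnects the network the alignment is not properly defined; its
#' correlation is still reported but flagged (and metrics are computed on
#' the giant component).
#'
#' @param surface A [surface_cloud()].
#' @param streamlines A [streamline_set()] (filtered if desired).
#' @param n_nodes Parcellation size N.
#' @param step Rotation step in degrees (default 10).
#' @param endpoint_radius_mm Passed to [build_dense_connectome()].
#' @param n_random,rewires_per_edge Random-ensemble size for the normalised
#'   metrics at each rotation.
#' @param restarts,iterations,cooling,seed Annealing controls, see
#'   [sa_align()].
#' @return A data frame of class `rotation_analysis`, one row per rotation
#'   (baseline 0 degrees first): `rotation`, `tx`, `ty`, `tz`, `nnz`,
#'   `n_components`, `connected`, `Cr`, `Lr`, `Q`, `r`.
#' @export
rotation_analysis <- function(surface, streamlines, n_nodes = 95,
                              step = 10, endpoint_radius_mm = 2,
                              n_random = 20, rewires_per_edge = 100,
                              restarts = 20L, iterations = 100L,
                              cooling = 0.955, seed = 1L) {
  surface <- surface_cloud(unclass(surface))
  dense <- build_dense_connectome(streamlines, surface, endpoint_radius_mm)
  rots <- list(c(0, 0, 0),
               c(step, 0, 0), c(-step, 0, 0),
               c(0, step, 0), c(0, -step, 0),
               c(0, 0, step), c(0, 0, -step))
  labels <- c("0", sprintf("%+gx", c(step, -step)),
              sprintf("%+gy", c(step, -step)), sprintf("%+gz", c(step, -step)))
  base_part <- equal_area_partition(n_nodes)
  nets <- lapply(rots, function(ang) {
    part <- rotate_partition(base_part, ang[1], ang[2], ang[3])
    refs <- scale_to_surface(part, surface)
    downscale(dense, assign_nodes(surface, refs))
  })
  net0 <- nets[[1]]
  rows <- lapply(seq_along(nets), function(k) {
    net <- nets[[k]]
    comp <- network_components(net)
    gm <- global_metrics(giant_component(net), n_random = n_random,
                         rewires_per_edge = rewires_per_edge,
                         seed = as.integer(seed) + 17L * k)
    r <- if (k == 1L) 1 else
      sa_align(net0, net, restarts = restarts, iterations = iterations,
               cooling = cooling, seed = as.integer(seed) + 31L * k)$r_after
    data.frame(rotation = labels[k], tx = rots[[k]][1], ty = rots[[k]][2],
               tz = rots[[k]][3], nnz = nnz(net),
               n_components = comp$n_components,
               connected = comp$n_components == 1L,
               Cr = gm$Cr, Lr = gm$Lr, Q = gm$Q, r = r)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rotation_analysis", "data.frame")
  out
}

#' @export
print.rotation_analysis <- function(x, ...) {
  shown <- data.frame(rotation = x$rotation, nnz = x$nnz,
                      components = x$n_components,
                      Cr = round(x$Cr, 2), Lr = round(x$Lr, 2),
                      Q = round(x$Q, 2),
                      r = ifelse(x$connected, sprintf("%.4f", x$r),
                                 sprintf("(%.4f)", x$r)))
  cat("rotation of the parcellation (r in parentheses: network disconnected,\n")
  cat("alignment not properly defined):\n")
  print(shown, row.names = FALSE)
  invisible(x)
}
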