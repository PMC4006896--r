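# Synthetic phantoms: surfaces, modular ground-truth networks, streamline
# sets and cohorts with known structure, so every pipeline stage can be
# tested without MRI data. All generators are bit-reproducible given a
# seed.

#' Generate a phantom surface
#'
#' Samples points area-uniformly on an ellipsoid (rejection sampling with
#' the surface-element weight), emulating the subcortical surface extracted
#' a few mm below the cortex. The default half-axes 60 x 80 x 50 mm are an
#' adult-brain-scale ellipsoid; equal half-axes give a sphere.
#'
#' @param n_points Number of surface points.
#' @param half_axes Ellipsoid half-axes (mm), length 3.
#' @param seed Integer seed (NULL: use the current RNG state).
#' @return A [surface_cloud()].
#' @export
make_surface <- function(n_points, half_axes = c(60, 80, 50), seed = NULL) {
  if (!is_count(n_points, min = 4)) stopf("n_points must be an integer >= 4")
  if (length(half_axes) != 3L || any(half_axes <= 0))
    stopf("half_axes must be 3 positive numbers")
  a <- half_axes[1]; b <- half_axes[2]; c_ <- half_axes[3]
  wmax <- max(a * b, b * c_, a * c_)
  with_seed(seed, {
    pts <- matrix(0, n_points, 3)
    got <- 0L
    while (got < n_points) {
      take <- max(64L, 2L * (n_points - got))
      u <- matrix(rnorm(3L * take), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      # ellipsoid area element relative to the sphere parametrisation
      w <- sqrt((b * c_ * u[, 1])^2 + (a * c_ * u[, 2])^2 +
                  (a * b * u[, 3])^2)
      acc <- runif(take) < w / wmax
      u <- u[acc, , drop = FALSE]
      if (nrow(u) == 0L) next
      n_new <- min(nrow(u), n_points - got)
      pts[got + seq_len(n_new), ] <-
        u[seq_len(n_new), , drop = FALSE] %*% diag(c(a, b, c_))
      got <- got + n_new
    }
    surface_cloud(pts)
  })
}

#' Generate a modular ground-truth network
#'
#' Planted-partition (stochastic block model) draw: nodes are split into
#' near-equal contiguous modules, each within-module pair is an edge with
#' probability `p_in` and each between-module pair with probability
#' `p_out`. This emulates the modular, small-world structure that the
#' normalised global metrics assume. If the draw is disconnected and
#' `connect = TRUE`, a ring through the lowest-indexed node of each
#' connected component is added and the repair is flagged (attribute
#' `connectivity_repaired` with the added edges in `repair_edges`); set
#' `connect = FALSE` to build deliberately disconnected phantoms.
#'
#' @param n_nodes Number of nodes (>= number of modules).
#' @param n_modules Number of planted modules.
#' @param p_in,p_out Within/between-module edge probabilities.
#' @param seed Integer seed.
#' @param connect Repair connectivity (default TRUE).
#' @return A [binary_network()] with attributes `modules` (node module
#'   ids), `connectivity_repaired`, `repair_edges`.
#' @export
make_ground_truth_network <- function(n_nodes, n_modules = 4, p_in = 0.8,
                                      p_out = 0.05, seed = NULL,
                                      connect = TRUE) {
  if (!is_count(n_nodes, min = 2)) stopf("n_nodes must be an integer >= 2")
  if (!is_count(n_modules) || n_modules > n_nodes)
    stopf("n_modules must be a positive integer <= n_nodes")
  if (any(c(p_in, p_out) < 0) || any(c(p_in, p_out) > 1))
    stopf("p_in and p_out must lie in [0, 1]")
  modules <- sort(rep_len(seq_len(n_modules), n_nodes))
  with_seed(seed, {
    adj <- matrix(0L, n_nodes, n_nodes)
    lt <- which(lower.tri(adj), arr.ind = TRUE)
    same <- modules[lt[, 1]] == modules[lt[, 2]]
    p <- ifelse(same, p_in, p_out)
    draw <- as.integer(runif(nrow(lt)) < p)
    adj[lt] <- draw
    adj <- adj + t(adj)
    repaired <- FALSE
    repair <- NULL
    if (connect) {
      net0 <- binary_network(adj)
      comp <- network_components(net0)
      if (comp$n_components > 1L) {
        repaired <- TRUE
        anchors <- vapply(seq_len(comp$n_components),
                          function(cid) min(which(comp$membership == cid)),
                          integer(1))
        ring <- cbind(anchors, c(anchors[-1], anchors[1]))
        ring <- ring[ring[, 1] != ring[, 2], , drop = FALSE]
        for (k in seq_len(nrow(ring)))
          adj[ring[k, 1], ring[k, 2]] <- adj[ring[k, 2], ring[k, 1]] <- 1L
        repair <- ring
      }
    }
    out <- binary_network(adj)
    attr(out, "modules") <- modules
    attr(out, "connectivity_repaired") <- repaired
    attr(out, "repair_edges") <- repair
    out
  })
}

#' Synthesize streamlines realising a ground-truth network
#'
#' The inverse of the connectome builder: for each ground-truth edge
#' (a, b), `streamlines_per_edge` polylines are emitted whose endpoints are
#' (optionally jittered) surface points belonging to nodes a and b. Each
#' polyline passes through a third point pulled toward the surface
#' centroid, so its length clears any realistic length threshold at brain
#' scale. With `endpoint_jitter_mm = 0`, rebuilding the dense connectome
#' and downscaling recovers the ground truth exactly; large jitter relative
#' to node spacing degrades recovery, reproducing the node-discretization
#' mechanism.
#'
#' @param net Ground-truth [binary_network()] at the assignment's N.
#' @param surface The [surface_cloud()] the assignment was made on.
#' @param assignment [assign_nodes()] result at the ground truth's N; every
#'   node with an edge must own at least one surface point.
#' @param streamlines_per_edge Streamlines per ground-truth edge.
#' @param endpoint_jitter_mm Gaussian noise (sd, mm) added to endpoints.
#' @param seed Integer seed.
#' @param endpoint_mode `"random"` (default): endpoints are drawn uniformly
#'   among the node's surface points; `"representative"`: always the node's
#'   lowest-indexed surface point (concentrating all connectivity in one
#'   point per node, which disconnects finer parcellations by design).
#' @return A [streamline_set()].
#' @export
synthesize_streamlines <- function(net, surface, assignment,
                                   streamlines_per_edge = 3,
                                   endpoint_jitter_mm = 0, seed = NULL,
                                   endpoint_mode = c("random",
                                                     "representative")) {
  stopifnot(inherits(net, "binary_network"),
            inherits(assignment, "node_assignment"))
  endpoint_mode <- match.arg(endpoint_mode)
  surface <- surface_cloud(unclass(surface))
  if (assignment$n != net$n)
    stopf("assignment has %d nodes but the network has %d",
          assignment$n, net$n)
  if (!is_count(streamlines_per_edge))
    stopf("streamlines_per_edge must be a positive integer")
  if (endpoint_jitter_mm < 0) stopf("endpoint_jitter_mm must be >= 0")
  lab <- assignment$labels
  members <- split(seq_along(lab), lab)
  edges <- which(lower.tri(net$adjacency) & net$adjacency == 1L,
                 arr.ind = TRUE)
  need <- unique(as.vector(edges))
  empty <- need[!as.character(need) %in% names(members)]
  if (length(empty))
    stopf("node %d has an edge but owns no surface points", empty[1])
  ctr <- colMeans(surface)
  with_seed(seed, {
    out <- vector("list", nrow(edges) * streamlines_per_edge)
    k <- 0L
    for (e in seq_len(nrow(edges))) {
      pa <- members[[as.character(edges[e, 2])]]
      pb <- members[[as.character(edges[e, 1])]]
      for (s in seq_len(streamlines_per_edge)) {
        ia <- if (endpoint_mode == "representative") pa[1] else
          pa[sample.int(length(pa), 1)]
        ib <- if (endpoint_mode == "representative") pb[1] else
          pb[sample.int(length(pb), 1)]
        p1 <- surface[ia, ]
        p2 <- surface[ib, ]
        if (endpoint_jitter_mm > 0) {
          p1 <- p1 + rnorm(3, sd = endpoint_jitter_mm)
          p2 <- p2 + rnorm(3, sd = endpoint_jitter_mm)
        }
        mid <- ctr + 0.25 * ((p1 + p2) / 2 - ctr)   # deep interior waypoint
        k <- k + 1L
        out[[k]] <- rbind(p1, mid, p2)
      }
    }
    streamline_set(out)
  })
}

#' Generate a phantom cohort
#'
#' Emulates within-group variability: each subject is the ground truth with
#' every lower-triangle entry independently flipped with probability
#' `edge_flip_rate`, then (optionally) node-permuted by a recorded random
#' permutation — the premise of network-domain alignment being that two
#' brains' networks are, to first order, node permutations of one another.
#'
#' @param net Base ground-truth [binary_network()].
#' @param n_subjects Number of subjects (>= 2).
#' @param edge_flip_rate Per-entry flip probability in \[0, 1\].
#' @param permute_nodes Apply a random node permutation per subject.
#' @param seed Integer seed.
#' @return List of subject bundles, each with `network`
#'   ([binary_network()]), `permutation` (applied node permutation;
#'   identity if `permute_nodes = FALSE`) and `n_flipped`.
#' @export
make_cohort <- function(net, n_subjects, edge_flip_rate = 0.05,
                        permute_nodes = TRUE, seed = NULL) {
  stopifnot(inherits(net, "binary_network"))
  if (!is_count(n_subjects, min = 2)) stopf("n_subjects must be >= 2")
  if (edge_flip_rate < 0 || edge_flip_rate > 1)
    stopf("edge_flip_rate must lie in [0, 1]")
  n <- net$n
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      base <- net$adjacency
      lt <- lower.tri(base)
      flips <- runif(sum(lt)) < edge_flip_rate
      v <- base[lt]
      v[flips] <- 1L - v[flips]
      adj <- base * 0L
      adj[lt] <- v
      adj <- adj + t(adj)
      perm <- if (permute_nodes) sample.int(n) else seq_len(n)
      list(network = binary_network(adj[perm, perm]),
           permutation = perm,
           n_flipped = sum(flips))
    })
  })
}

#' Generate a two-group phantom cohort with a planted contrast
#'
#' Both groups are drawn as in [make_cohort()] (without node permutation:
#' subjects are taken as already aligned to a common reference), but in
#' every group-B subject the given contrast edges are toggled relative to
#' the base network, planting a coherent edge-wise group difference for
#' power studies of [nbs()] and [fdr_correct()].
#'
#' @param net Base ground-truth [binary_network()].
#' @param n_per_group Subjects per group (>= 2).
#' @param edge_flip_rate Per-entry noise flip probability.
#' @param contrast_edges k-by-2 matrix of node pairs toggled in group B;
#'   defaults to [planted_path_edges()] of length 6.
#' @param seed Integer seed.
#' @return List with `group_a`, `group_b` (lists of [binary_network()])
#'   and `contrast_edges`.
#' @export
make_two_group_cohort <- function(net, n_per_group, edge_flip_rate = 0.05,
                                  contrast_edges = planted_path_edges(net),
                                  seed = NULL) {
  stopifnot(inherits(net, "binary_network"))
  contrast_edges <- as.matrix(contrast_edges)
  if (ncol(contrast_edges) != 2L || any(contrast_edges < 1) ||
      any(contrast_edges > net$n))
    stopf("contrast_edges must be a k x 2 matrix of node indices")
  alt <- net$adjacency
  for (k in seq_len(nrow(contrast_edges))) {
    i <- contrast_edges[k, 1]; j <- contrast_edges[k, 2]
    alt[i, j] <- alt[j, i] <- 1L - alt[i, j]
  }
  with_seed(seed, {
    draw <- function(base) {
      lapply(seq_len(n_per_group), function(s) {
        cohort_noise(base, edge_flip_rate)
      })
    }
    list(group_a = draw(net$adjacency),
         group_b = draw(alt),
         contrast_edges = contrast_edges)
  })
}

cohort_noise <- function(adj, rate) {
  lt <- lower.tri(adj)
  v <- adj[lt]
  flips <- runif(length(v)) < rate
  v[flips] <- 1L - v[flips]
  out <- adj * 0L
  out[lt] <- v
  binary_network(out + t(out))
}

#' Edges of a path through the first nodes of a network
#'
#' Convenience contrast for planted group differences: the 6-edge path
#' 1-2-3-...-7 (or shorter/longer via `length`).
#'
#' @param net A [binary_network()] (used only for its size check).
#' @param length Number of edges in the path.
#' @return A `length`-by-2 matrix of node pairs.
#' @export
planted_path_edges <- function(net, length = 6L) {
  stopifnot(inherits(net, "binary_network"))
  if (length + 1L > net$n)
    stopf("network too small for a %d-edge path", length)
  cbind(seq_len(length), seq_len(length) + 1L)
}
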