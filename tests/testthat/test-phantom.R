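# Synthetic phantom generators: surfaces, ground-truth networks,
# streamlines and cohorts, plus the module's defining round-trip oracle.

test_that("spherical surfaces have constant radius; ellipsoids match half-axes", {
  s <- make_surface(1000, half_axes = c(70, 70, 70), seed = 1)
  r <- sqrt(rowSums(unclass(s)^2))
  expect_lt(max(abs(r - 70)), 1e-9)

  e <- make_surface(4000, half_axes = c(60, 80, 50), seed = 2)
  rng <- apply(unclass(e), 2, function(x) max(abs(x)))
  expect_equal(rng, c(60, 80, 50), tolerance = 0.05)
  # on-ellipsoid invariant holds exactly
  q <- sweep(unclass(e), 2, c(60, 80, 50), "/")
  expect_lt(max(abs(rowSums(q^2) - 1)), 1e-9)
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(make_surface(200, seed = 3), make_surface(200, seed = 3))
  expect_identical(make_ground_truth_network(20, 3, 0.7, 0.1, seed = 4),
                   make_ground_truth_network(20, 3, 0.7, 0.1, seed = 4))
  n <- make_ground_truth_network(20, 3, 0.7, 0.1, seed = 4)
  surf <- make_surface(300, seed = 3)
  asg <- assign_nodes(surf, scale_to_surface(equal_area_partition(20), surf))
  expect_identical(synthesize_streamlines(n, surf, asg, 2, 0.5, seed = 5),
                   synthesize_streamlines(n, surf, asg, 2, 0.5, seed = 5))
})

test_that("planted-partition generator produces the expected block structure", {
  two <- make_ground_truth_network(12, 2, 1, 0, seed = 6)
  mods <- attr(two, "modules")
  within <- two$adjacency[mods == 1, mods == 1]
  expect_true(all(within[lower.tri(within)] == 1))  # clique
  # metrics confirm strong modularity
  gm <- global_metrics(giant_component(two), n_random = 10,
                       rewires_per_edge = 10, seed = 7)
  expect_gt(gm$Q, 0.3)

  # degenerate case p_in = p_out = p behaves like G(N, p): edge count in
  # a generous binomial band
  flat <- make_ground_truth_network(40, 4, 0.3, 0.3, seed = 8,
                                    connect = FALSE)
  m <- sum(flat$adjacency) / 2
  expect_gt(m, qbinom(0.0005, choose(40, 2), 0.3))
  expect_lt(m, qbinom(0.9995, choose(40, 2), 0.3))
})

test_that("connectivity repair is flagged and produces a connected network", {
  # p = 0 draw: only the repair ring can connect it
  iso <- make_ground_truth_network(10, 2, 0, 0, seed = 9)
  expect_true(attr(iso, "connectivity_repaired"))
  expect_equal(network_components(iso)$n_components, 1)
  # and can be disabled for deliberately disconnected phantoms
  off <- make_ground_truth_network(10, 2, 0, 0, seed = 9, connect = FALSE)
  expect_equal(network_components(off)$n_components, 10)
})

test_that("jitter-free streamlines round-trip to the exact ground truth", {
  for (seed in 1:6) {
    n_true <- 15 + 3 * seed
    surf <- make_surface(600, seed = seed)
    asg <- assign_nodes(surf,
                        scale_to_surface(equal_area_partition(n_true), surf))
    gt <- make_ground_truth_network(n_true, 2 + seed %% 3, 0.7, 0.05,
                                    seed = 100 + seed)
    ss <- synthesize_streamlines(gt, surf, asg,
                                 streamlines_per_edge = 1 + seed %% 3,
                                 endpoint_jitter_mm = 0, seed = 200 + seed)
    rec <- downscale(build_dense_connectome(ss, surf, 2), asg)
    expect_identical(rec$adjacency, gt$adjacency)
    expect_true(all(rec$weights[gt$adjacency == 1] >= 1 + seed %% 3))
  }
})

test_that("synthesized streamlines clear the adult length threshold", {
  surf <- make_surface(500, seed = 10)
  asg <- assign_nodes(surf, scale_to_surface(equal_area_partition(20), surf))
  gt <- make_ground_truth_network(20, 3, 0.8, 0.1, seed = 11)
  ss <- synthesize_streamlines(gt, surf, asg, 2, 0, seed = 12)
  lens <- vapply(unclass(ss), streamline_length, numeric(1))
  expect_gt(min(lens), 15)
})

test_that("heavy jitter degrades recovery (node-discretization mechanism)", {
  surf <- make_surface(600, seed = 13)
  asg <- assign_nodes(surf, scale_to_surface(equal_area_partition(25), surf))
  gt <- make_ground_truth_network(25, 3, 0.7, 0.05, seed = 14)
  ss <- synthesize_streamlines(gt, surf, asg, 2, endpoint_jitter_mm = 25,
                               seed = 15)
  rec <- downscale(build_dense_connectome(ss, surf, 60), asg)
  inter <- sum(rec$adjacency & gt$adjacency) / 2
  union <- sum(rec$adjacency | gt$adjacency) / 2
  expect_lt(inter / union, 1)   # edge Jaccard below 1
})

test_that("an edge into a point-less node is reported by name", {
  surf <- make_surface(200, seed = 16)
  asg <- assign_nodes(surf, scale_to_surface(equal_area_partition(10), surf))
  asg$n <- 11L   # node 11 exists but owns no points
  adj <- matrix(0L, 11, 11); adj[1, 11] <- adj[11, 1] <- 1L
  gt <- binary_network(adj)
  expect_error(synthesize_streamlines(gt, surf, asg, 1, 0, seed = 17),
               "node 11")
})

test_that("cohort flips follow the Bernoulli contract and record permutations", {
  base <- make_ground_truth_network(30, 3, 0.6, 0.1, seed = 18)
  coh <- make_cohort(base, n_subjects = 40, edge_flip_rate = 0.05,
                     permute_nodes = FALSE, seed = 19)
  m <- choose(30, 2)
  flips <- vapply(coh, function(s) s$n_flipped, numeric(1))
  hamming <- vapply(coh, function(s)
    sum(abs(s$network$adjacency - base$adjacency)) / 2, numeric(1))
  expect_equal(flips, hamming)   # no permutation: flips are the distance
  # mean flips within 4 binomial standard errors of 0.05 * m
  se <- sqrt(m * 0.05 * 0.95 / length(coh))
  expect_lt(abs(mean(flips) - 0.05 * m), 4 * se)

  perm <- make_cohort(base, 3, edge_flip_rate = 0, permute_nodes = TRUE,
                      seed = 20)
  for (s in perm) {
    expect_identical(s$network$adjacency,
                     base$adjacency[s$permutation, s$permutation])
    # recorded permutation undoes the subject: alignment oracle target
    inv <- order(s$permutation)
    expect_identical(s$network$adjacency[inv, inv], base$adjacency)
  }
})

test_that("pure-permutation cohorts align back to r = 1", {
  base <- half_graph(22)
  coh <- make_cohort(base, 3, edge_flip_rate = 0, permute_nodes = TRUE,
                     seed = 21)
  for (s in coh) {
    al <- sa_align(base, s$network, restarts = 20, iterations = 150,
                   seed = 22)
    expect_equal(al$cost, 0)
    expect_equal(al$r_after, 1)
  }
})
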