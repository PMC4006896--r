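# Simulated-annealing matrix alignment, lower-triangle correlation,
# reference selection, sum networks and the rotation analysis.

test_that("lower triangle has N(N-1)/2 entries", {
  expect_length(lower_triangle(matrix(0, 100, 100)), 4950)
  expect_length(lower_triangle(matrix(0, 95, 95)), 4465)
})

test_that("lower-triangle Pearson correlation: identity, anti-correlation, errors", {
  net <- er_network(12, 0.4, 1)
  expect_equal(pearson_lower_triangle(net, net), 1)

  comp <- binary_network(1L - net$adjacency - diag(1L, 12))
  expect_equal(pearson_lower_triangle(net, comp), -1)

  expect_error(pearson_lower_triangle(net, er_network(10, 0.4, 1)),
               "equal N|differ in size")
  empty <- binary_network(matrix(0L, 12, 12))
  expect_error(pearson_lower_triangle(net, empty), "constant")
})

test_that("correlation is invariant under a common permutation", {
  a <- er_network(15, 0.3, 2)
  b <- er_network(15, 0.3, 3)
  r0 <- pearson_lower_triangle(a, b)
  for (seed in 1:5) {
    p <- with_seed_local(seed, sample(15))
    expect_equal(pearson_lower_triangle(
      binary_network(a$adjacency[p, p]),
      binary_network(b$adjacency[p, p])), r0, tolerance = 1e-12)
  }
})

test_that("self-alignment returns cost 0 and correlation 1", {
  net <- er_network(20, 0.3, 4)
  al <- sa_align(net, net, restarts = 5, seed = 1)
  expect_equal(al$cost, 0)
  expect_equal(al$r_after, 1)
  expect_equal(al$permutation, 1:20)
})

test_that("alignment never does worse than the identity permutation", {
  for (seed in 1:10) {
    a <- er_network(20, 0.3, 100 + seed)
    b <- er_network(20, 0.3, 200 + seed)
    al <- sa_align(a, b, restarts = 10, iterations = 50, seed = seed)
    id_cost <- sum(abs(a$adjacency - b$adjacency))
    expect_lte(al$cost, id_cost)
    expect_gte(al$r_after, al$r_before)
  }
})

test_that("SA matches the exhaustive-permutation oracle at N = 7", {
  hits <- 0
  for (seed in 1:20) {
    a <- er_network(7, 0.4, 300 + seed)
    b <- binary_network(with_seed_local(400 + seed, {
      p <- sample(7)
      m <- a$adjacency[p, p]
      # toggle one edge so the optimum is usually nonzero
      m[1, 2] <- m[2, 1] <- 1L - m[1, 2]
      m
    }))
    bf <- brute_force_align(a, b)
    sa <- sa_align(a, b, restarts = 50, iterations = 100, seed = seed)
    expect_gte(sa$cost, bf$cost)   # oracle is the true minimum
    if (sa$cost == bf$cost) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("a permuted copy is recovered exactly when degrees are distinctive", {
  net <- half_graph(24)
  expect_equal(length(unique(colSums(net$adjacency))), 23)  # max distinct
  for (seed in 1:5) {
    p <- with_seed_local(seed, sample(24))
    moved <- binary_network(net$adjacency[p, p])
    al <- sa_align(net, moved, restarts = 20, iterations = 150, seed = seed)
    expect_equal(al$cost, 0)
    expect_equal(al$r_after, 1)
    # recovered permutation undoes the applied one
    expect_identical(moved$adjacency[al$permutation, al$permutation],
                     net$adjacency)
  }
})

test_that("pairwise group alignment fills a directional correlation matrix", {
  net <- er_network(15, 0.35, 7)
  two <- pairwise_align_group(list(net, net), restarts = 5, seed = 1)
  expect_equal(two$r_matrix, matrix(1, 2, 2))

  # permuted copies of one ground truth align to r = 1 everywhere
  subj <- lapply(1:4, function(s) {
    p <- with_seed_local(500 + s, sample(20))
    binary_network(half_graph(20)$adjacency[p, p])
  })
  grp <- pairwise_align_group(subj, restarts = 20, iterations = 150, seed = 2)
  expect_equal(grp$r_matrix, matrix(1, 4, 4))
  expect_equal(diag(grp$r_matrix), rep(1, 4))
})

test_that("reference selection picks the most typical subject", {
  # planted typical member: subject 3 is the base; others are noisy copies
  base <- er_network(30, 0.3, 11)
  subj <- with_seed_local(12, {
    noisy <- lapply(1:3, function(s) {
      adj <- base$adjacency
      lt <- which(lower.tri(adj))
      flip <- sample(lt, round(0.05 * length(lt)))
      adj[flip] <- 1L - adj[flip]
      adj[upper.tri(adj)] <- 0L
      adj <- adj + t(adj); diag(adj) <- 0L
      binary_network(adj)
    })
    c(noisy[1:2], list(base), noisy[3])
  })
  grp <- pairwise_align_group(subj, restarts = 10, iterations = 100, seed = 3)
  # brute-force mean-r comparison
  means <- (rowSums(grp$r_matrix) - 1) / 3
  expect_equal(select_reference(grp), which.max(means))
  expect_equal(select_reference(grp), 3L)

  # all-identical cohort: tie broken to subject 1
  same <- pairwise_align_group(list(base, base, base), restarts = 3, seed = 4)
  expect_equal(select_reference(same), 1L)
})

test_that("sum network counts subjects possessing each aligned connection", {
  net <- er_network(12, 0.4, 13)
  grp <- pairwise_align_group(list(net, net, net, net), restarts = 3, seed = 5)
  sn <- sum_network(grp)
  expect_true(all(sn$counts %in% c(0L, 4L)))
  expect_equal((sn$counts >= 1) * 1L, net$adjacency * 1L)

  # permuted cohort of one ground truth: counts in {0, S} after alignment
  subj <- lapply(1:4, function(s) {
    p <- with_seed_local(600 + s, sample(18))
    binary_network(half_graph(18)$adjacency[p, p])
  })
  grp2 <- pairwise_align_group(subj, restarts = 20, iterations = 150, seed = 6)
  sn2 <- sum_network(grp2)
  expect_true(all(sn2$counts %in% c(0L, 4L)))
  expect_equal(max(sn2$counts), 4L)
  expect_equal(diag(sn2$counts), rep(0L, 18))
})

test_that("rotation analysis reports a baseline row with r = 1 and six rotations", {
  surf <- make_surface(900, seed = 41)
  part <- equal_area_partition(30)
  asg <- assign_nodes(surf, scale_to_surface(part, surf))
  gt <- make_ground_truth_network(30, 3, 0.75, 0.05, seed = 42)
  ss <- synthesize_streamlines(gt, surf, asg, 2, 0, seed = 43)
  ra <- rotation_analysis(surf, ss, n_nodes = 30, step = 10,
                          n_random = 5, rewires_per_edge = 10,
                          restarts = 10, iterations = 80, seed = 44)
  expect_equal(nrow(ra), 7)  # baseline + 2 rotations per axis
  expect_equal(ra$rotation[1], "0")
  expect_equal(ra$r[1], 1)
  expect_equal(ra$nnz[1], nnz(downscale(build_dense_connectome(ss, surf, 2),
                                        asg)))
  # rotating the parcellation shifts node borders: connection count changes
  expect_true(any(ra$nnz[-1] != ra$nnz[1]))
})
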