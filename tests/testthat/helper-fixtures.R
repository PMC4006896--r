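# Fixtures built in code; no stored data files.

# Erdos-Renyi adjacency matrix as a binary_network.
er_network <- function(n, p, seed) {
  with_seed_local(seed, {
    adj <- matrix(0L, n, n)
    lt <- lower.tri(adj)
    adj[lt] <- as.integer(runif(sum(lt)) < p)
    binary_network(adj + t(adj))
  })
}

# Ring lattice: each node connected to its k nearest neighbours (k/2 per
# side). Local clustering for k = 4 is exactly 1/2.
ring_lattice <- function(n, k) {
  adj <- matrix(0L, n, n)
  for (d in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + d) %% n) + 1
      adj[i, j] <- adj[j, i] <- 1L
    }
  }
  binary_network(adj)
}

# "Half graph": edge i~j iff i + j > n. Maximally distinct degree sequence
# (one unavoidable tie, exchanged by an automorphism), connected.
half_graph <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (i + j > n) adj[i, j] <- adj[j, i] <- 1L
  binary_network(adj)
}

complete_network <- function(n) {
  adj <- matrix(1L, n, n) - diag(1L, n)
  binary_network(adj)
}

# Seed helper usable from helpers (mirrors the package-internal one).
with_seed_local <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bernoulli edge-flip noise on an adjacency matrix, using the current RNG.
cohort_noise_adj <- function(adj, rate) {
  lt <- lower.tri(adj)
  v <- adj[lt]
  flips <- runif(length(v)) < rate
  v[flips] <- 1L - v[flips]
  out <- adj * 0L
  out[lt] <- as.integer(v)
  binary_network(out + t(out))
}

# Independent union-find component oracle on an adjacency matrix.
uf_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (adj[i, j] == 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Write a minimal TrackVis .trk file (built at test time, never stored).
write_trk <- function(streamlines, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("TRACK"), con); writeBin(as.raw(0), con)
  writeBin(c(2L, 2L, 2L), con, size = 2)                  # dim
  writeBin(rep(1, 6), con, size = 4)                      # voxel_size, origin
  writeBin(0L, con, size = 2)                             # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2)                             # n_properties
  writeBin(raw(200), con)
  writeBin(raw(1000 - 440 - 12), con)
  writeBin(length(streamlines), con, size = 4)            # n_count
  writeBin(2L, con, size = 4)                             # version
  writeBin(1000L, con, size = 4)                          # hdr_size
  for (s in streamlines) {
    writeBin(nrow(s), con, size = 4)
    writeBin(as.numeric(t(s)), con, size = 4)
  }
  invisible(path)
}
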