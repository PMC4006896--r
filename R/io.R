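# Readers and writers for the package's plain-text formats. All files are
# 0-based on disk (point, node and streamline ids); in-memory objects use
# R's 1-based indexing.

#' Surface point cloud
#'
#' Validates an ordered set of 3-D points (mm) representing the subcortical
#' surface, the point set the dense connectome is defined on. Point identity
#' is positional: point k is row k.
#'
#' @param points Numeric n-by-3 matrix, n >= 4, all coordinates finite.
#' @return The matrix with class `surface_cloud`.
#' @export
surface_cloud <- function(points) {
  check_xyz_matrix(points, "surface")
  if (nrow(points) < 4L)
    stopf("a surface needs at least 4 points, got %d", nrow(points))
  dimnames(points) <- NULL
  structure(points, class = c("surface_cloud", "matrix", "array"))
}

#' @export
print.surface_cloud <- function(x, ...) {
  rng <- apply(x, 2, range)
  cat(sprintf("surface_cloud: %d points, extent x [%.1f, %.1f] y [%.1f, %.1f] z [%.1f, %.1f] mm\n",
              nrow(x), rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2],
              rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Read a surface point cloud
#'
#' Whitespace-separated text, one `x y z` triple (mm) per line; lines
#' starting with `#` and blank lines are skipped. Points keep file order.
#'
#' @param path Path to the surface file.
#' @return A [surface_cloud()].
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stopf("surface file not found: %s", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stopf("surface file %s contains no points", path)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  nfield <- lengths(parts)
  if (any(nfield != 3L))
    stopf("surface file %s: line %d has %d fields, expected 3 (x y z)",
          path, keep[which(nfield != 3L)[1L]], nfield[nfield != 3L][1L])
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (anyNA(vals)) {
    bad <- keep[ceiling(which(is.na(vals))[1L] / 3)]
    stopf("surface file %s: line %d is not numeric", path, bad)
  }
  surface_cloud(matrix(vals, ncol = 3L, byrow = TRUE))
}

#' Write a surface point cloud
#'
#' @param surface A [surface_cloud()] or n-by-3 matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  surface <- surface_cloud(unclass(surface))
  writeLines(c("# x y z (mm)",
               apply(surface, 1, function(p)
                 paste(formatC(p, format = "g", digits = 17), collapse = "\t"))),
             path)
  invisible(path)
}

#' Streamline set
#'
#' A list of polylines (n-by-3 point matrices, mm, >= 2 points each) in the
#' same coordinate frame as the surface.
#'
#' @param streamlines List of numeric matrices with 3 columns.
#' @return The list with class `streamline_set`.
#' @export
streamline_set <- function(streamlines) {
  if (!is.list(streamlines)) stopf("streamlines must be a list of matrices")
  for (k in seq_along(streamlines)) {
    check_xyz_matrix(streamlines[[k]], sprintf("streamline %d", k))
    if (nrow(streamlines[[k]]) < 2L)
      stopf("streamline %d has fewer than 2 points", k)
    dimnames(streamlines[[k]]) <- NULL
  }
  structure(streamlines, class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  np <- vapply(x, nrow, integer(1))
  cat(sprintf("streamline_set: %d streamlines, %d points total\n",
              length(x), sum(np)))
  invisible(x)
}

#' Read streamlines
#'
#' The native dialect is a TSV with header columns `streamline_id`,
#' `point_order`, `x`, `y`, `z`; rows are grouped by id (ascending) and
#' ordered by `point_order` within each streamline. TrackVis `.trk` files
#' are supported as an optional dialect; their points are read as stored,
#' without interpreting orientation metadata (the framework deliberately
#' deemphasizes anatomical location).
#'
#' @param path Path to the streamline file.
#' @param dialect `"tsv"` (native, default) or `"trk"`.
#' @return A [streamline_set()].
#' @export
read_streamlines <- function(path, dialect = c("tsv", "trk")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("streamline file not found: %s", path)
  if (dialect == "trk") return(read_trk(path))
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "numeric")
  req <- c("streamline_id", "point_order", "x", "y", "z")
  if (!all(req %in% names(d)))
    stopf("streamline TSV %s must have columns: %s", path,
          paste(req, collapse = ", "))
  if (nrow(d) == 0L) return(streamline_set(list()))
  ids <- sort(unique(d$streamline_id))
  out <- lapply(ids, function(id) {
    rows <- d[d$streamline_id == id, , drop = FALSE]
    if (nrow(rows) < 2L)
      stopf("streamline %s has a single point (>= 2 required)",
            format(id))
    rows <- rows[order(rows$point_order), , drop = FALSE]
    as.matrix(rows[, c("x", "y", "z")])
  })
  streamline_set(out)
}

#' Write streamlines (native TSV)
#'
#' @param streamlines A [streamline_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(streamlines, path) {
  streamlines <- streamline_set(unclass(streamlines))
  np <- vapply(streamlines, nrow, integer(1))
  d <- data.frame(
    streamline_id = rep(seq_along(streamlines) - 1L, np),  # 0-based on disk
    point_order = unlist(lapply(np, seq_len)) - 1L,
    do.call(rbind, streamlines))
  names(d)[3:5] <- c("x", "y", "z")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Minimal TrackVis .trk reader (format version 2, 1000-byte header).
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- rawToChar(readBin(con, "raw", 6))
  if (!startsWith(id, "TRACK")) stopf("%s is not a TrackVis .trk file", path)
  readBin(con, "integer", 3, size = 2)           # dim
  readBin(con, "numeric", 6, size = 4)           # voxel_size, origin
  n_scalars <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)                       # scalar names
  n_properties <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)                       # property names
  readBin(con, "raw", 1000 - 440 - 12)           # rest of header up to counts
  n_count <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 4)           # version
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size != 1000L) stopf("%s: unexpected .trk header size %d", path, hdr_size)
  out <- list()
  repeat {
    npts <- readBin(con, "integer", 1, size = 4)
    if (length(npts) == 0L) break
    vals <- readBin(con, "numeric", npts * (3L + n_scalars), size = 4)
    if (n_properties > 0) readBin(con, "numeric", n_properties, size = 4)
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    out[[length(out) + 1L]] <- m
    if (n_count > 0 && length(out) >= n_count) break
  }
  streamline_set(out)
}

#' Read an adjacency (or streamline-count) matrix
#'
#' CSV of N rows by N columns of non-negative integers, no header. A matrix
#' with entries above 1 is interpreted as streamline counts and binarized at
#' a threshold of 1 streamline, keeping the counts as weights.
#'
#' @param path Path to the CSV file.
#' @return A [binary_network()].
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stopf("adjacency file not found: %s", path)
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  if (!is.numeric(m) || anyNA(m)) stopf("%s: adjacency must be numeric", path)
  if (nrow(m) != ncol(m))
    stopf("%s: adjacency must be square (got %d x %d)", path, nrow(m), ncol(m))
  if (any(m < 0) || any(m != floor(m)))
    stopf("%s: adjacency entries must be non-negative integers", path)
  if (!isTRUE(all.equal(m, t(m))))
    stopf("%s: adjacency must be symmetric", path)
  if (any(diag(m) != 0))
    stopf("%s: adjacency must have a zero diagonal", path)
  if (any(m > 1))
    binary_network((m >= 1) * 1L, weights = m)
  else
    binary_network(m)
}

#' Write a network's adjacency or weight matrix as CSV
#'
#' @param net A [binary_network()].
#' @param path Output path.
#' @param what `"adjacency"` (default) or `"weights"`.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(net, path, what = c("adjacency", "weights")) {
  stopifnot(inherits(net, "binary_network"))
  what <- match.arg(what)
  m <- net[[what]]
  if (is.null(m)) stopf("network carries no %s matrix", what)
  write.table(m, path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Collects the tunable parameters of the pipeline with the defaults used
#' for adult-scale data: candidate node counts 10...3000, minimum streamline
#' length 15 mm (5 mm is appropriate for neonates, 10 mm for 6-month-old
#' infants), endpoint-to-surface association radius 2 mm, 100 annealing
#' restarts, and 100 degree-preserving random networks with every edge
#' rewired 1000 times.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    node_counts_to_try = c(10L, 50L, 90L, 95L, 100L, 105L, 110L, 150L,
                           300L, 500L, 1000L, 3000L),
    min_streamline_length_mm = 15,
    endpoint_radius_mm = 2,
    sa_restarts = 100L,
    sa_iterations = 200L,
    cooling_factor = 0.955,
    random_seed = 1L,
    n_random_networks = 100L,
    rewires_per_edge = 1000L
  ), class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Fields present in the file override [default_run_config()]; unknown
#' fields are an error.
#'
#' @param path Path to a JSON file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- default_run_config()
  user <- jsonlite::fromJSON(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stopf("unknown config fields: %s", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  nc <- cfg$node_counts_to_try
  if (length(nc) == 0 || any(nc < 1) || any(nc != floor(nc)) ||
      is.unsorted(nc, strictly = TRUE))
    stopf("node_counts_to_try must be strictly increasing positive integers")
  if (cfg$min_streamline_length_mm < 0)
    stopf("min_streamline_length_mm must be non-negative")
  if (cfg$endpoint_radius_mm <= 0)
    stopf("endpoint_radius_mm must be positive")
  if (cfg$cooling_factor <= 0 || cfg$cooling_factor >= 1)
    stopf("cooling_factor must lie in (0, 1)")
  for (f in c("sa_restarts", "sa_iterations", "n_random_networks",
              "rewires_per_edge"))
    if (!is_count(cfg[[f]])) stopf("%s must be a positive integer", f)
  cfg$node_counts_to_try <- as.integer(nc)
  structure(cfg, class = "run_config")
}
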