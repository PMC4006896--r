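# From streamlines to networks: length filtering, the dense point-to-point
# connectome, and downscaling to the N-by-N binary network.

#' Length of a streamline
#'
#' Sum of Euclidean segment lengths of a polyline.
#'
#' @param polyline Numeric matrix with 3 columns and at least 2 rows (mm).
#' @return Length in mm.
#' @export
#' @examples
#' streamline_length(rbind(c(0, 0, 0), c(3, 4, 0))) # 5
streamline_length <- function(polyline) {
  check_xyz_matrix(polyline, "polyline")
  if (nrow(polyline) < 2L)
    stopf("a streamline needs at least 2 points")
  d <- diff(polyline)
  sum(sqrt(rowSums(d^2)))
}

#' Filter streamlines by minimum length
#'
#' Streamline length thresholding compensates for noise in the diffusion
#' data and the oversimplification of tensor modelling: short spurious
#' streamlines are removed before network construction. Thresholds of
#' 5 mm (neonates), 10 mm (6-month-old infants) and 15 mm (adults) are the
#' reference choices for brain-scale data.
#'
#' @param streamlines A [streamline_set()].
#' @param min_length_mm Minimum length to keep (>= 0); a streamline is kept
#'   iff its length is >= the threshold.
#' @return A list with `streamlines` (the kept [streamline_set()], input
#'   order preserved) and `report` (counts `n_input`, `n_kept`, `n_removed`,
#'   `threshold_mm`).
#' @export
filter_by_length <- function(streamlines, min_length_mm) {
  streamlines <- streamline_set(unclass(streamlines))
  if (!is.numeric(min_length_mm) || length(min_length_mm) != 1L ||
      !is.finite(min_length_mm) || min_length_mm < 0)
    stopf("min_length_mm must be a non-negative number")
  len <- vapply(streamlines, streamline_length, numeric(1))
  keep <- len >= min_length_mm
  list(
    streamlines = streamline_set(unclass(streamlines)[keep]),
    report = list(n_input = length(keep),
                  n_kept = sum(keep),
                  n_removed = sum(!keep),
                  threshold_mm = min_length_mm)
  )
}

#' Build the dense connectome from streamline endpoints
#'
#' Each streamline's two endpoints are mapped to the nearest surface point;
#' if both map within `endpoint_radius_mm` and to two distinct points i and
#' j, the unordered pair (i, j) is counted as connected by one more
#' streamline. Streamlines with an unmapped endpoint, or with both
#' endpoints at the same surface point, contribute nothing (their counts
#' are reported in the attached log).
#'
#' @param streamlines A [streamline_set()] (typically length-filtered).
#' @param surface A [surface_cloud()].
#' @param endpoint_radius_mm Maximum endpoint-to-surface-point distance for
#'   an endpoint to be considered as touching the surface (default 2 mm,
#'   about one voxel).
#' @return A [dense_connectome()] with attribute `log` (a list with
#'   `n_streamlines`, `n_mapped`, `n_unmapped`, `n_self`).
#' @export
build_dense_connectome <- function(streamlines, surface,
                                   endpoint_radius_mm = 2) {
  streamlines <- streamline_set(unclass(streamlines))
  surface <- surface_cloud(unclass(surface))
  if (!is.numeric(endpoint_radius_mm) || endpoint_radius_mm <= 0)
    stopf("endpoint_radius_mm must be positive")
  ns <- length(streamlines)
  np <- nrow(surface)
  if (ns == 0L) {
    out <- dense_connectome(np, data.frame(i = integer(), j = integer(),
                                           count = integer()))
    attr(out, "log") <- list(n_streamlines = 0L, n_mapped = 0L,
                             n_unmapped = 0L, n_self = 0L)
    return(out)
  }

  ends <- matrix(0, 2L * ns, 3L)
  for (k in seq_len(ns)) {
    s <- streamlines[[k]]
    ends[2L * k - 1L, ] <- s[1L, ]
    ends[2L * k, ] <- s[nrow(s), ]
  }
  # nearest surface point per endpoint (blocked to bound memory)
  nearest <- integer(2L * ns)
  ndist <- numeric(2L * ns)
  surf_sq <- rowSums(surface^2)
  block <- 2048L
  for (start in seq(1L, nrow(ends), by = block)) {
    idx <- start:min(start + block - 1L, nrow(ends))
    p <- ends[idx, , drop = FALSE]
    d2 <- outer(rowSums(p^2), surf_sq, "+") - 2 * (p %*% t(surface))
    nearest[idx] <- max.col(-d2, ties.method = "first")
    ndist[idx] <- sqrt(pmax(0, d2[cbind(seq_along(idx), nearest[idx])]))
  }
  within <- ndist <= endpoint_radius_mm
  a <- nearest[seq(1L, 2L * ns, by = 2L)]
  b <- nearest[seq(2L, 2L * ns, by = 2L)]
  ok <- within[seq(1L, 2L * ns, by = 2L)] & within[seq(2L, 2L * ns, by = 2L)]
  self <- ok & (a == b)
  use <- ok & (a != b)

  i <- pmin(a[use], b[use])
  j <- pmax(a[use], b[use])
  if (length(i)) {
    key <- (i - 1) * as.double(np) + j
    tab <- table(key)
    keyv <- as.numeric(names(tab))
    pairs <- data.frame(i = as.integer((keyv - 1) %/% np + 1),
                        j = as.integer((keyv - 1) %% np + 1),
                        count = as.integer(tab))
    pairs <- pairs[order(pairs$i, pairs$j), ]
  } else {
    pairs <- data.frame(i = integer(), j = integer(), count = integer())
  }
  out <- dense_connectome(np, pairs)
  attr(out, "log") <- list(n_streamlines = ns, n_mapped = sum(use),
                           n_unmapped = sum(!ok), n_self = sum(self))
  out
}

#' Downscale a dense connectome to the N-by-N binary network
#'
#' Combines dense connectome entries by node label: the weight between
#' nodes a and b is the total streamline count over point pairs (i, j) with
#' labels \{a, b\}, a != b; point pairs inside one node are discarded (zero
#' diagonal). Two nodes are connected in the binary adjacency if at least
#' one connecting streamline is present.
#'
#' @param dense A [dense_connectome()].
#' @param assignment A [assign_nodes()] result covering all surface points.
#' @param surface Optional [surface_cloud()]; when given, per-node centroid
#'   coordinates are attached to the network for plotting.
#' @return A [binary_network()] with streamline-count weights.
#' @export
downscale <- function(dense, assignment, surface = NULL) {
  stopifnot(inherits(dense, "dense_connectome"),
            inherits(assignment, "node_assignment"))
  if (length(assignment$labels) < dense$n_points)
    stopf("assignment covers %d points but the dense connectome has %d",
          length(assignment$labels), dense$n_points)
  n <- assignment$n
  lab <- assignment$labels
  if (any(lab < 1L) || any(lab > n)) stopf("node label out of range 1..%d", n)
  w <- matrix(0L, n, n)
  if (nrow(dense$pairs)) {
    a <- lab[dense$pairs$i]
    b <- lab[dense$pairs$j]
    keep <- a != b
    if (any(keep)) {
      lo <- pmin(a[keep], b[keep])
      hi <- pmax(a[keep], b[keep])
      cnt <- dense$pairs$count[keep]
      for (k in seq_along(lo)) {
        w[lo[k], hi[k]] <- w[lo[k], hi[k]] + cnt[k]
      }
      w[lower.tri(w)] <- t(w)[lower.tri(w)]
    }
  }
  coords <- NULL
  if (!is.null(surface)) {
    surface <- surface_cloud(unclass(surface))
    coords <- matrix(NA_real_, n, 3)
    for (k in unique(lab))
      coords[k, ] <- colMeans(surface[lab == k, , drop = FALSE])
  }
  binary_network((w >= 1L) * 1L, weights = w, node_coords = coords)
}
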