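# Equal-area partitioning of the unit sphere and its use as an individual,
# atlas-free parcellation: the sphere is scaled to each subject's surface
# and every surface point is assigned to the nearest region center.

#' Partition the unit sphere into N regions of equal area
#'
#' Recursive zonal equal-area partitioning: two polar caps of area
#' `4*pi/N` plus latitudinal collars, each collar divided into equal-area
#' longitude cells. Collar boundaries are placed so that the spherical cap
#' above the k-th region boundary has area exactly `k * 4*pi/N`, which makes
#' every region's area exactly `4*pi/N` by construction. Region centers
#' (the node reference points) sit at the colatitude midpoint of their zone
#' and the longitude midpoint of their cell; the construction is fully
#' deterministic.
#'
#' Regions are numbered from the north cap (region 1), then collars from
#' north to south (within a collar, by increasing longitude), to the south
#' cap (region N).
#'
#' @param n Number of regions (N >= 1).
#' @return An object of class `sphere_partition` with elements `n`,
#'   `centers` (N-by-3 unit vectors), `zone_counts` (regions per zone),
#'   `colat_bounds` (zone colatitude boundaries, radians), `rotation`
#'   (applied Euler angles, degrees) and `rotation_matrix`.
#' @seealso [rotate_partition()], [scale_to_surface()],
#'   [partition_region_index()], [partition_region_areas()]
#' @export
#' @examples
#' p <- equal_area_partition(95)
#' range(partition_region_areas(p)) # all 4*pi/95
equal_area_partition <- function(n) {
  if (!is_count(n)) stopf("n must be a positive integer (got %s)", format(n))
  n <- as.integer(n)

  if (n == 1L) {
    zone_counts <- 1L
    colat_bounds <- c(0, pi)
  } else if (n == 2L) {
    zone_counts <- c(1L, 1L)
    colat_bounds <- c(0, pi / 2, pi)
  } else {
    theta_c <- 2 * asin(sqrt(1 / n))          # polar cap colatitude, area 4*pi/n
    delta_i <- sqrt(4 * pi / n)               # ideal collar angle
    n_collars <- max(1L, as.integer(round((pi - 2 * theta_c) / delta_i)))
    delta_f <- (pi - 2 * theta_c) / n_collars

    # ideal (real-valued) region counts per collar, rounded so the running
    # discrepancy never exceeds one region and the total is exact
    counts <- integer(n_collars)
    resid <- 0
    for (i in seq_len(n_collars)) {
      a <- theta_c + (i - 1) * delta_f
      y <- n * (cos(a) - cos(a + delta_f)) / 2
      counts[i] <- as.integer(round(y + resid))
      resid <- resid + y - counts[i]
    }
    counts[n_collars] <- counts[n_collars] + (n - 2L - sum(counts))
    if (any(counts < 1L)) stopf("degenerate collar in partition for n = %d", n)
    zone_counts <- c(1L, counts, 1L)
    # exact equal-area boundaries from cumulative region counts
    kcum <- cumsum(zone_counts)
    colat_bounds <- c(0, acos(pmin(1, pmax(-1, 1 - 2 * kcum / n))))
    colat_bounds[length(colat_bounds)] <- pi
  }

  centers <- .zone_centers(zone_counts, colat_bounds)
  structure(list(n = n, centers = centers, zone_counts = zone_counts,
                 colat_bounds = colat_bounds,
                 rotation = c(0, 0, 0), rotation_matrix = diag(3)),
            class = "sphere_partition")
}

.zone_centers <- function(zone_counts, colat_bounds) {
  rows <- vector("list", length(zone_counts))
  for (z in seq_along(zone_counts)) {
    m <- zone_counts[z]
    top <- colat_bounds[z]
    bot <- colat_bounds[z + 1]
    if (z == 1L && top == 0) {
      rows[[z]] <- matrix(c(0, 0, 1), 1)
      next
    }
    if (z == length(zone_counts) && bot >= pi) {
      rows[[z]] <- matrix(c(0, 0, -1), 1)
      next
    }
    th <- (top + bot) / 2
    phi <- 2 * pi * (seq_len(m) - 0.5) / m
    rows[[z]] <- cbind(sin(th) * cos(phi), sin(th) * sin(phi),
                       rep(cos(th), m))
  }
  do.call(rbind, rows)
}

#' @export
print.sphere_partition <- function(x, ...) {
  cat(sprintf("sphere_partition: N = %d regions (area 4*pi/N = %.6f sr each), %d zones\n",
              x$n, 4 * pi / x$n, length(x$zone_counts)))
  if (any(x$rotation != 0))
    cat(sprintf("  rotated by (%.1f, %.1f, %.1f) degrees about x, y, z\n",
                x$rotation[1], x$rotation[2], x$rotation[3]))
  invisible(x)
}

#' Analytic region areas of a sphere partition
#'
#' Exact area of each region from its zone boundaries: a zone between
#' colatitudes a and b has area `2*pi*(cos a - cos b)`, split evenly among
#' its longitude cells. Equals `4*pi/N` for every region by construction.
#'
#' @param partition A [equal_area_partition()].
#' @return Numeric vector of N region areas (steradian).
#' @export
partition_region_areas <- function(partition) {
  stopifnot(inherits(partition, "sphere_partition"))
  zc <- partition$zone_counts
  cb <- partition$colat_bounds
  zone_area <- 2 * pi * (cos(cb[-length(cb)]) - cos(cb[-1]))
  rep(zone_area / zc, zc)
}

#' Region membership of points on the sphere
#'
#' Maps unit vectors (or any nonzero vectors, which are normalized) to the
#' index of the equal-area region containing them, honouring any rotation
#' applied to the partition. This is the partition's own region definition
#' (colatitude zone and longitude cell), used e.g. to verify area
#' uniformity by Monte-Carlo sampling.
#'
#' @param partition A [equal_area_partition()].
#' @param points Numeric m-by-3 matrix of directions.
#' @return Integer vector of region indices in 1..N.
#' @export
partition_region_index <- function(partition, points) {
  stopifnot(inherits(partition, "sphere_partition"))
  check_xyz_matrix(points, "points")
  u <- points %*% partition$rotation_matrix   # back to the unrotated frame
  r <- sqrt(rowSums(u^2))
  if (any(r == 0)) stopf("cannot assign the zero vector to a region")
  u <- u / r
  colat <- acos(pmin(1, pmax(-1, u[, 3])))
  cb <- partition$colat_bounds
  nz <- length(partition$zone_counts)
  zone <- findInterval(colat, cb[-c(1, length(cb))]) + 1L
  zone <- pmin(zone, nz)
  m <- partition$zone_counts[zone]
  offset <- cumsum(c(0L, partition$zone_counts))[zone]
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  cell <- pmin(m - 1L, floor(phi / (2 * pi) * m))
  as.integer(offset + cell + 1L)
}

#' Rotate the reference sphere of a partition
#'
#' Applies the rotation `Rz(tz) %*% Ry(ty) %*% Rx(tx)` (angles in degrees)
#' to all region centers and records it, composing with any rotation already
#' applied. Rotating the parcellation sphere shifts every node boundary on
#' the brain surface and is used to quantify the node-discretization error;
#' a 10 degree step shifts a 95-node parcellation by about half a node.
#'
#' @param partition A [equal_area_partition()].
#' @param tx,ty,tz Rotation angles about the x, y and z axes, degrees.
#' @return The rotated `sphere_partition`.
#' @export
rotate_partition <- function(partition, tx = 0, ty = 0, tz = 0) {
  stopifnot(inherits(partition, "sphere_partition"))
  if (!all(is.finite(c(tx, ty, tz)))) stopf("rotation angles must be finite")
  r <- rotation_matrix_xyz(tx, ty, tz)
  partition$centers <- partition$centers %*% t(r)
  partition$rotation_matrix <- r %*% partition$rotation_matrix
  partition$rotation <- partition$rotation + c(tx, ty, tz)
  partition
}

#' Rotation matrix Rz(tz) Ry(ty) Rx(tx) from angles in degrees
#'
#' @param tx,ty,tz Angles in degrees.
#' @return A 3-by-3 rotation matrix.
#' @export
rotation_matrix_xyz <- function(tx = 0, ty = 0, tz = 0) {
  a <- tx * pi / 180; b <- ty * pi / 180; c_ <- tz * pi / 180
  rx <- matrix(c(1, 0, 0,
                 0, cos(a), -sin(a),
                 0, sin(a), cos(a)), 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b),
                 0, 1, 0,
                 -sin(b), 0, cos(b)), 3, byrow = TRUE)
  rz <- matrix(c(cos(c_), -sin(c_), 0,
                 sin(c_), cos(c_), 0,
                 0, 0, 1), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

#' Scale a sphere partition to an individual surface
#'
#' Maps each (possibly rotated) unit-sphere region center c_k to
#' `centroid(surface) + diag(sx, sy, sz) %*% c_k`, where `(sx, sy, sz)` are
#' the per-axis half-ranges of the surface. The scaled points serve as the
#' node reference points on this subject's brain.
#'
#' @param partition A [equal_area_partition()].
#' @param surface A [surface_cloud()].
#' @return N-by-3 matrix of node reference points (mm).
#' @export
scale_to_surface <- function(partition, surface) {
  stopifnot(inherits(partition, "sphere_partition"))
  surface <- surface_cloud(unclass(surface))
  rng <- apply(surface, 2, range)
  half <- (rng[2, ] - rng[1, ]) / 2
  if (any(half <= 0))
    stopf("degenerate surface: zero extent along axis %s",
          paste(which(half <= 0), collapse = ", "))
  ctr <- colMeans(surface)
  sweep(partition$centers %*% diag(half), 2, ctr, "+")
}

#' Assign surface points to the nearest node reference point
#'
#' Every surface point gets the label of the closest scaled reference point
#' (Euclidean distance, ties broken by the lowest node index). Nodes whose
#' region of the brain surface contains no points receive no labels and end
#' up isolated in the downscaled network — this is deliberate, since
#' isolated nodes are what drives the optimal-N selection.
#'
#' @param surface A [surface_cloud()].
#' @param refs N-by-3 matrix of node reference points from
#'   [scale_to_surface()].
#' @return An object of class `node_assignment` with elements `labels`
#'   (per-point node index, 1..N) and `n` (node count).
#' @export
assign_nodes <- function(surface, refs) {
  surface <- surface_cloud(unclass(surface))
  check_xyz_matrix(refs, "refs")
  n <- nrow(refs)
  if (n < 1L) stopf("need at least one reference point")
  labels <- integer(nrow(surface))
  ref_sq <- rowSums(refs^2)
  block <- 2048L
  for (start in seq(1L, nrow(surface), by = block)) {
    idx <- start:min(start + block - 1L, nrow(surface))
    p <- surface[idx, , drop = FALSE]
    d2 <- outer(rowSums(p^2), ref_sq, "+") - 2 * (p %*% t(refs))
    labels[idx] <- max.col(-d2, ties.method = "first")
  }
  structure(list(labels = labels, n = n), class = "node_assignment")
}

#' @export
print.node_assignment <- function(x, ...) {
  used <- length(unique(x$labels))
  cat(sprintf("node_assignment: %d points over %d nodes (%d nodes non-empty)\n",
              length(x$labels), x$n, used))
  invisible(x)
}
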