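# Internal helpers shared across modules.

# Run expr with a locally set RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x) && x >= min
}

check_xyz_matrix <- function(x, what) {
  if (!is.matrix(x) || ncol(x) != 3L || !is.numeric(x))
    stopf("%s must be a numeric matrix with 3 columns (x, y, z)", what)
  if (!all(is.finite(x)))
    stopf("%s contains non-finite coordinates", what)
  invisible(x)
}

#' Strictly-sub-diagonal entries of a square matrix
#'
#' Extracts the N(N-1)/2 entries below the diagonal, the element set over
#' which all network correlations and edge-wise tests in this package
#' operate (for N = 100 that is 4950 entries, for N = 95 it is 4465).
#' Entries are returned in column-major order.
#'
#' @param m A square matrix, or a [binary_network()].
#' @return Numeric vector of length `N*(N-1)/2`.
#' @export
#' @examples
#' length(lower_triangle(diag(95))) # 4465
lower_triangle <- function(m) {
  if (inherits(m, "binary_network")) m <- m$adjacency
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stopf("lower_triangle() expects a square matrix")
  m[lower.tri(m)]
}
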