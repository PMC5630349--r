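# Connectivity-matrix construction and sparsity-based binarization.

#' Fisher-z connectivity matrix from regional time series
#'
#' Computes the Pearson correlation between every pair of ROI series
#' over the retained frames and applies the variance-stabilising Fisher
#' r-to-z transform `z = atanh(r)`. The diagonal is set to 0 and is
#' excluded from all downstream edge ranking.
#'
#' @param ts an [roi_ts] with at least 3 retained frames.
#' @return Symmetric numeric matrix of Fisher-z values with attributes
#'   `labels` and `id`.
#' @export
connectivity_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  x <- ts$signal
  if (ncol(x) < 3)
    stop_input("need at least 3 retained frames to estimate correlations")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop_input("zero-variance ROI(s): ",
               paste(ts$labels[sds == 0], collapse = ", "))
  r <- stats::cor(t(x))
  off <- r[upper.tri(r)]
  if (any(abs(off) >= 1))
    stop_input("degenerate |r| = 1 between distinct ROIs (duplicate or sign-flipped series)")
  z <- atanh(r)
  diag(z) <- 0
  attr(z, "labels") <- ts$labels
  attr(z, "id") <- ts$id
  z
}

# Pair ordering used for edge ranking: decreasing |z|, ties broken by
# (i, j) lexicographic order. Returns the upper-triangle linear indices
# in rank order.
rank_pairs <- function(z) {
  n <- nrow(z)
  ut <- which(upper.tri(z))
  ii <- row(z)[ut]
  jj <- col(z)[ut]
  ut[order(-abs(z[ut]), ii, jj)]
}

#' Binarize a connectivity matrix at a target sparsity
#'
#' Keeps the `K = round(sparsity * N(N-1)/2)` node pairs with the
#' largest absolute Fisher-z values (so strong negative couplings also
#' become edges) and discards the rest, yielding an undirected,
#' unweighted adjacency matrix with exactly `K` edges. Rank ties at the
#' K-th edge are broken deterministically by (row, column) order.
#'
#' @param z symmetric Fisher-z (or any symmetric weight) matrix.
#' @param sparsity target edge density in (0, 1): realised edges over
#'   the `N(N-1)/2` possible pairs.
#' @return Binary adjacency matrix with attribute `sparsity` (the
#'   realised value `K / (N(N-1)/2)`).
#' @export
#' @examples
#' z <- matrix(0, 4, 4); z[1, 2] <- z[2, 1] <- 3
#' z[3, 4] <- z[4, 3] <- 2; z[1, 3] <- z[3, 1] <- 1
#' binarize_at_sparsity(z, 0.5)  # keeps the 3 strongest of 6 pairs
binarize_at_sparsity <- function(z, sparsity) {
  if (!is.matrix(z) || nrow(z) != ncol(z))
    stop_input("z must be a square matrix")
  if (any(z != t(z))) stop_input("z must be symmetric")
  if (!is.numeric(sparsity) || sparsity <= 0 || sparsity >= 1)
    stop_input("sparsity must lie strictly between 0 and 1")
  n <- nrow(z)
  n_pairs <- n * (n - 1) / 2
  k <- round(sparsity * n_pairs)
  if (k == 0)
    stop_input(sprintf("sparsity %g yields an empty graph on %d nodes", sparsity, n))
  keep <- rank_pairs(z)[seq_len(k)]
  adj <- matrix(0, n, n)
  adj[keep] <- 1
  adj <- adj + t(adj)
  dimnames(adj) <- dimnames(z)
  attr(adj, "sparsity") <- k / n_pairs
  adj
}

#' Minimum sparsity ensuring a connected-regime mean degree
#'
#' Scans the sparsity grid (multiples of `step`) upward and returns the
#' first value `s` at which the mean degree of the thresholded network,
#' `s * (N - 1)`, exceeds `2 * ln(N)` -- the usual estimability floor
#' for sparse graph metrics.
#'
#' @param n_nodes node count (>= 4).
#' @param step grid resolution (default 0.01).
#' @return The smallest admissible sparsity on the grid.
#' @export
#' @examples
#' minimum_sparsity(90)  # 0.11
minimum_sparsity <- function(n_nodes, step = 0.01) {
  if (!is_count(n_nodes) || n_nodes < 4) stop_input("n_nodes must be >= 4")
  target <- 2 * log(n_nodes)
  for (m in seq_len(ceiling(1 / step))) {
    s <- m * step
    if (s * (n_nodes - 1) > target) return(s)
  }
  stop_input("no sparsity below 1 satisfies the mean-degree criterion")
}

#' Maximum sparsity preserving small-worldness across all subjects
#'
#' Given each subject's small-worldness sigma at every grid point,
#' returns the largest grid value such that the minimum sigma over
#' subjects stays above `sigma_floor` at every grid point up to and
#' including it.
#'
#' @param sigma matrix of sigma values, subjects in rows, one column
#'   per grid point.
#' @param grid numeric vector of sparsity values (columns of `sigma`).
#' @param sigma_floor small-worldness floor (default 1.1).
#' @return The largest admissible sparsity on the grid.
#' @export
maximum_sparsity <- function(sigma, grid, sigma_floor = 1.1) {
  sigma <- as.matrix(sigma)
  if (ncol(sigma) != length(grid))
    stop_input("sigma must have one column per grid point")
  if (anyNA(sigma)) stop_input("sigma contains missing values")
  ok <- apply(sigma, 2, function(col) all(col > sigma_floor))
  if (!ok[1])
    stop_input(sprintf(
      "small-worldness criterion fails at the first grid point (s = %g); choose a different grid",
      grid[1]))
  first_fail <- match(FALSE, ok)
  if (is.na(first_fail)) grid[length(grid)] else grid[first_fail - 1]
}

#' Sparsity grid
#'
#' Uniformly spaced threshold sequence used for all curve and AUC
#' computations. Defaults to the 0.11-0.44 range at 0.01 resolution.
#'
#' @param min,max,step grid range and resolution.
#' @return Numeric vector of sparsity values.
#' @export
sparsity_grid <- function(min = 0.11, max = 0.44, step = 0.01) {
  if (min >= max) stop_input("min must be below max")
  round(seq(min, max, by = step), 10)
}
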