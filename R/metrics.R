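# Global and nodal graph metrics on binary undirected networks,
# small-world normalization against degree-preserving rewired nulls,
# and AUC summaries across the sparsity grid.
#
# Graphs are plain 0/1 symmetric adjacency matrices; igraph backs the
# shortest-path, betweenness and rewiring primitives.

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(check_adjacency(adj),
                                      mode = "undirected", diag = FALSE)
}

#' Nodal and mean clustering coefficients
#'
#' For each node i with degree `K_i`, the fraction of realised edges
#' among its neighbours, `E_i / (K_i (K_i - 1) / 2)`; nodes with fewer
#' than two neighbours have no neighbour pairs and score 0, keeping the
#' network mean well defined at low sparsity. The network clustering
#' `C_p` is the unweighted mean over all nodes.
#'
#' @param adj binary adjacency matrix.
#' @return List with `ci` (per-node vector) and `cp` (mean).
#' @export
#' @examples
#' tri <- matrix(0, 4, 4)
#' tri[cbind(c(1, 1, 2, 1), c(2, 3, 3, 4))] <- 1
#' tri <- tri + t(tri)
#' clustering_coef(tri)$ci  # 1/3, 1, 1, 0
clustering_coef <- function(adj) {
  adj <- check_adjacency(adj)
  deg <- rowSums(adj)
  triangles <- diag(adj %*% adj %*% adj)  # 2 * edges among neighbours
  denom <- deg * (deg - 1)
  ci <- ifelse(denom > 0, triangles / denom, 0)
  list(ci = as.numeric(ci), cp = mean(ci))
}

#' Hop-distance matrix
#'
#' Breadth-first shortest-path lengths between all node pairs;
#' unreachable pairs are `Inf`.
#'
#' @param adj binary adjacency matrix.
#' @return Numeric `N x N` matrix of hop counts, zero diagonal.
#' @export
distance_matrix <- function(adj) {
  d <- igraph::distances(as_igraph(adj), algorithm = "unweighted")
  dimnames(d) <- dimnames(adj)
  d
}

#' Characteristic path length
#'
#' Per node, the mean of the finite hop distances to all other nodes;
#' infinite (unreachable) distances are excluded from the mean and
#' counted. `L_p` is the mean of the defined per-node values; isolated
#' nodes (no finite distance to any other node) are flagged undefined
#' and excluded from `L_p` with a warning.
#'
#' @param adj binary adjacency matrix, or a precomputed distance matrix
#'   via `dist_mat`.
#' @param dist_mat optional distance matrix to reuse.
#' @return List with `li` (per-node means, `NA` when undefined), `lp`,
#'   and `n_unreachable` (count of excluded node pairs, ordered).
#' @export
path_length <- function(adj, dist_mat = NULL) {
  d <- if (is.null(dist_mat)) distance_matrix(adj) else dist_mat
  n <- nrow(d)
  diag(d) <- NA
  finite <- is.finite(d)
  n_unreachable <- sum(!finite & !is.na(d))
  li <- vapply(seq_len(n), function(i) {
    vals <- d[i, ][finite[i, ] %in% TRUE]
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, numeric(1))
  if (anyNA(li))
    warning(sprintf("%d isolated node(s) excluded from the path-length mean",
                    sum(is.na(li))))
  list(li = li, lp = mean(li, na.rm = TRUE), n_unreachable = n_unreachable)
}

#' Global efficiency
#'
#' Mean over all ordered node pairs of the inverse hop distance, with
#' `1/Inf = 0` for unreachable pairs -- well defined on disconnected
#' graphs, equal to 1 only on the complete graph.
#'
#' @inheritParams path_length
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adj, dist_mat = NULL) {
  d <- if (is.null(dist_mat)) distance_matrix(adj) else dist_mat
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' For each node i, the mean inverse hop distance to every other node
#' (`1/Inf = 0`): the node's capacity for parallel information exchange
#' with the rest of the network. The mean of the nodal efficiencies
#' equals the global efficiency.
#'
#' @inheritParams path_length
#' @return Numeric vector of per-node efficiencies in `[0, 1]`.
#' @export
nodal_efficiency <- function(adj, dist_mat = NULL) {
  d <- if (is.null(dist_mat)) distance_matrix(adj) else dist_mat
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  as.numeric(rowSums(inv) / (n - 1))
}

#' Local efficiency
#'
#' For each node i, the global efficiency of the subgraph induced on
#' i's neighbours (i itself excluded); nodes with fewer than two
#' neighbours contribute 0. The network value is the mean over all
#' nodes -- a fault-tolerance measure: how well each neighbourhood
#' exchanges information if its hub node is removed.
#'
#' @param adj binary adjacency matrix.
#' @return List with `nodal` (per-node neighbourhood efficiencies) and
#'   `eloc` (network mean).
#' @export
local_efficiency <- function(adj) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  nodal <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  list(nodal = nodal, eloc = mean(nodal))
}

#' Betweenness centrality
#'
#' For each node i, the sum over node pairs (s, t), each unordered pair
#' counted once, of the fraction of shortest s-t paths passing through
#' i (Brandes algorithm). Unnormalized by default; `normalized = TRUE`
#' divides by `(N-1)(N-2)/2`.
#'
#' @param adj binary adjacency matrix.
#' @param normalized divide by the number of possible pairs?
#' @return Numeric vector of per-node betweenness values.
#' @export
betweenness_centrality <- function(adj, normalized = FALSE) {
  bc <- igraph::betweenness(as_igraph(adj), directed = FALSE,
                            normalized = FALSE)
  if (normalized) {
    n <- nrow(adj)
    bc <- bc / ((n - 1) * (n - 2) / 2)
  }
  as.numeric(bc)
}

#' Degree-preserving rewiring (null-model randomization)
#'
#' Markov-chain randomization by repeated double-edge swaps: two edges
#' (a,b), (c,d) are replaced by (a,d), (c,b), rejecting any swap that
#' would create a self-loop or duplicate edge. The degree sequence and
#' edge count are invariant; triangles (and hence clustering) are
#' destroyed as mixing proceeds.
#'
#' @param adj binary adjacency matrix with at least 2 edges.
#' @param n_swaps number of attempted swaps; defaults to 10 times the
#'   edge count, a standard mixing budget.
#' @param seed optional integer seed.
#' @return Rewired adjacency matrix with the same degree sequence.
#' @export
rewire_degree_preserving <- function(adj, n_swaps = NULL, seed = NULL) {
  adj <- check_adjacency(adj)
  n_edges <- sum(adj) / 2
  if (n_edges < 2) stop_input("rewiring needs at least 2 edges")
  if (is.null(n_swaps)) n_swaps <- 10 * n_edges
  g <- as_igraph(adj)
  g2 <- local_seed(seed,
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                             niter = n_swaps)))
  out <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  dimnames(out) <- dimnames(adj)
  out
}

# C_p and L_p of one igraph object, used in the null loop. L_p follows
# the package-wide exclusion rule (per-node means over finite
# distances, isolated nodes dropped); NA only when every node is
# isolated.
cp_lp_igraph <- function(g) {
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  d <- igraph::distances(g, algorithm = "unweighted")
  diag(d) <- NA
  li <- rowMeans(ifelse(is.finite(d), d, NA), na.rm = TRUE)
  li[!is.finite(li)] <- NA
  if (all(is.na(li))) return(c(mean(ci), NA_real_))
  c(mean(ci), mean(li, na.rm = TRUE))
}

#' Small-world indices against degree-preserving nulls
#'
#' Generates `n_random` degree-preserving rewired null networks and
#' returns the normalized clustering `gamma = C_p / mean(C_random)`,
#' normalized path length `lambda = L_p / mean(L_random)`, and the
#' small-worldness scalar `sigma = gamma / lambda`. A network is
#' conventionally called small-world when `gamma > 1`, `lambda ~ 1`,
#' i.e. `sigma > 1` (the pipeline's threshold-selection rule requires
#' `sigma > 1.1`). Nulls whose path length is undefined (an isolated
#' node) are regenerated with a fresh sub-seed, up to 10 retries each.
#'
#' @param adj binary adjacency matrix.
#' @param n_random number of null networks (default 100).
#' @param seed optional integer seed.
#' @param n_swaps attempted swaps per null (default 10 x edge count).
#' @return List with `gamma`, `lambda`, `sigma`, `cp`, `lp`,
#'   `c_random`, `l_random`.
#' @export
small_world_indices <- function(adj, n_random = 100, seed = NULL,
                                n_swaps = NULL) {
  adj <- check_adjacency(adj)
  g <- as_igraph(adj)
  real <- cp_lp_igraph(g)
  if (!is.finite(real[2]))
    stop_input("path length undefined on the input graph (isolated node)")
  n_edges <- sum(adj) / 2
  if (is.null(n_swaps)) n_swaps <- 10 * n_edges
  base_seed <- if (is.null(seed)) NULL else seed
  c_rand <- l_rand <- numeric(n_random)
  for (r in seq_len(n_random)) {
    val <- c(NA_real_, NA_real_)
    for (attempt in 0:10) {
      sub_seed <- if (is.null(base_seed)) NULL
                  else derive_seed(base_seed, r, attempt)
      g_null <- local_seed(sub_seed,
        igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = n_swaps)))
      val <- cp_lp_igraph(g_null)
      if (is.finite(val[2])) break
    }
    if (!is.finite(val[2]))
      stop_input("null network path length undefined after 10 retries")
    c_rand[r] <- val[1]
    l_rand[r] <- val[2]
  }
  gamma <- real[1] / mean(c_rand)
  lambda <- real[2] / mean(l_rand)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       cp = real[1], lp = real[2],
       c_random = mean(c_rand), l_random = mean(l_rand))
}

#' All nodal metrics of one graph
#'
#' Convenience wrapper computing degree, clustering, mean finite hop
#' distance, nodal efficiency, neighbourhood (local) efficiency and
#' betweenness for every node.
#'
#' @param adj binary adjacency matrix.
#' @return Data frame, one row per node.
#' @export
nodal_metrics <- function(adj) {
  adj <- check_adjacency(adj)
  d <- distance_matrix(adj)
  pl <- suppressWarnings(path_length(adj, dist_mat = d))
  data.frame(
    node = seq_len(nrow(adj)),
    degree = rowSums(adj),
    clustering = clustering_coef(adj)$ci,
    path_length = pl$li,
    efficiency = nodal_efficiency(adj, dist_mat = d),
    local_efficiency = local_efficiency(adj)$nodal,
    betweenness = betweenness_centrality(adj)
  )
}

#' All global metrics of one graph
#'
#' Computes `C_p`, `L_p`, global and local efficiency, and -- when
#' `n_random > 0` -- the small-world indices `gamma`, `lambda`,
#' `sigma` against degree-preserving nulls.
#'
#' @param adj binary adjacency matrix.
#' @param n_random null networks for the small-world indices (0 skips
#'   them).
#' @param seed optional integer seed for the null generation.
#' @return Named list of global metrics.
#' @export
global_metrics <- function(adj, n_random = 0, seed = NULL) {
  adj <- check_adjacency(adj)
  d <- distance_matrix(adj)
  pl <- suppressWarnings(path_length(adj, dist_mat = d))
  out <- list(
    cp = clustering_coef(adj)$cp,
    lp = pl$lp,
    eglo = global_efficiency(adj, dist_mat = d),
    eloc = local_efficiency(adj)$eloc,
    gamma = NA_real_, lambda = NA_real_, sigma = NA_real_
  )
  if (n_random > 0) {
    sw <- small_world_indices(adj, n_random = n_random, seed = seed)
    out$gamma <- sw$gamma
    out$lambda <- sw$lambda
    out$sigma <- sw$sigma
  }
  out
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral of a metric sampled on the uniform sparsity
#' grid: `sum_k (Y(S_k) + Y(S_k+1)) * dS / 2`. Gives a threshold-free
#' scalar summary of the curve.
#'
#' @param values metric values at the grid points.
#' @param grid uniform, strictly increasing sparsity grid (>= 2
#'   points).
#' @return The AUC scalar.
#' @export
#' @examples
#' g <- sparsity_grid()
#' metric_auc(rep(2, length(g)), g)  # 2 * 0.33 = 0.66
metric_auc <- function(values, grid) {
  if (length(grid) < 2) stop_input("need at least 2 grid points")
  if (length(values) != length(grid))
    stop_input("values and grid lengths differ")
  steps <- diff(grid)
  if (any(steps <= 0) || max(steps) - min(steps) > 1e-8)
    stop_input("grid must be strictly increasing with uniform step")
  ds <- steps[1]
  n <- length(values)
  sum((values[-n] + values[-1]) * ds / 2)
}

#' Cost-efficiency curve and its maximum
#'
#' Pointwise difference between the global-efficiency curve and the
#' cost (sparsity) itself; positive values indicate an economical
#' network. Returns the difference curve and the grid point maximising
#' it (first point on ties, with a flag).
#'
#' @param eglo global-efficiency values on the grid.
#' @param grid sparsity grid.
#' @return List with `difference`, `argmax` (sparsity value),
#'   `max` (difference there) and `tie` (logical).
#' @export
cost_efficiency <- function(eglo, grid) {
  if (length(eglo) != length(grid))
    stop_input("eglo and grid lengths differ")
  diff_curve <- eglo - grid
  best <- max(diff_curve)
  at <- which(diff_curve == best)
  list(difference = diff_curve, argmax = grid[at[1]], max = best,
       tie = length(at) > 1)
}
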