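# Independent brute-force oracles for graph metrics, deliberately
# implemented with different algorithms than the package (Floyd-
# Warshall distances, matrix-power shortest-path counting, direct
# neighbour-edge loops) so that agreement is a genuine cross-check.

# Floyd-Warshall all-pairs hop distances.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Clustering by directly counting edges among each node's neighbours.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    e <- 0
    for (a in seq_along(nb))
      for (b in seq_len(a - 1))
        e <- e + adj[nb[a], nb[b]]
    e / (k * (k - 1) / 2)
  })
}

# Per-node mean finite distance; NA when a node reaches nothing.
oracle_path_length <- function(adj) {
  d <- oracle_distances(adj)
  diag(d) <- NA
  li <- apply(d, 1, function(row) {
    v <- row[is.finite(row)]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  list(li = li, lp = mean(li, na.rm = TRUE))
}

oracle_global_efficiency <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_nodal_efficiency <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  per_node <- sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  })
  list(nodal = per_node, eloc = mean(per_node))
}

# Betweenness via shortest-path counting with matrix powers:
# the number of shortest s-t paths is (A^d(s,t))[s,t], and the number
# through i is the product of the two leg counts when the distances
# compose.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  maxd <- max(d[is.finite(d)])
  powers <- vector("list", max(maxd, 1))
  powers[[1]] <- adj
  if (maxd >= 2)
    for (p in 2:maxd) powers[[p]] <- powers[[p - 1]] %*% adj
  n_paths <- function(s, t) {
    if (s == t) return(1)
    if (!is.finite(d[s, t])) return(0)
    powers[[d[s, t]]][s, t]
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1))
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      tot <- n_paths(s, t)
      for (i in seq_len(n)) {
        if (i == s || i == t) next
        if (is.finite(d[s, i]) && is.finite(d[i, t]) &&
            d[s, i] + d[i, t] == d[s, t])
          bc[i] <- bc[i] + n_paths(s, i) * n_paths(i, t) / tot
      }
    }
  bc
}

# Random simple undirected graph; optionally resampled until connected.
random_graph <- function(n, p = 0.5, connected = FALSE) {
  repeat {
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
    adj <- adj + t(adj)
    if (!connected) return(adj)
    if (all(is.finite(oracle_distances(adj)))) return(adj)
  }
}

# Small named fixtures used across test files.
path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
star4 <- {
  s <- matrix(0, 4, 4); s[1, 2:4] <- 1; s + t(s)
}
complete_graph <- function(n) {
  adj <- matrix(1, n, n); diag(adj) <- 0; adj
}
triangle_pendant <- {
  # triangle 1-2-3 plus pendant edge 1-4
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[1, 3] <- a[2, 3] <- a[1, 4] <- 1
  a + t(a)
}
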