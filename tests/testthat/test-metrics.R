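# Graph metrics: hand-computed fixtures, brute-force oracle agreement,
# null-model rewiring, small-world indices, AUC and cost efficiency.

test_that("clustering matches hand counts on canonical graphs", {
  expect_equal(clustering_coef(complete_graph(5))$ci, rep(1, 5))
  expect_equal(clustering_coef(complete_graph(5))$cp, 1)
  s5 <- matrix(0, 5, 5); s5[1, 2:5] <- 1; s5 <- s5 + t(s5)
  expect_equal(clustering_coef(s5)$ci, rep(0, 5))  # star: no triangles
  expect_equal(clustering_coef(triangle_pendant)$ci, c(1 / 3, 1, 1, 0))
  expect_equal(clustering_coef(triangle_pendant)$cp, 7 / 12)
})

test_that("distances and path length follow hop counts with finite-mean exclusion", {
  expect_equal(distance_matrix(path3)[1, 3], 2)
  two_tri <- matrix(0, 6, 6)
  two_tri[1:3, 1:3] <- complete_graph(3)
  two_tri[4:6, 4:6] <- complete_graph(3)
  expect_true(all(is.infinite(distance_matrix(two_tri)[1:3, 4:6])))

  pl <- path_length(path3)
  expect_equal(pl$li, c(1.5, 1, 1.5))
  expect_equal(pl$lp, 4 / 3)
  expect_equal(path_length(complete_graph(4))$lp, 1)

  # isolated node: excluded from the mean with a warning
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_warning(pl_iso <- path_length(iso), "isolated")
  expect_true(is.na(pl_iso$li[3]))
  expect_equal(pl_iso$lp, 1)
})

test_that("efficiencies match hand computations and each other", {
  expect_equal(global_efficiency(complete_graph(6)), 1)
  expect_equal(global_efficiency(path3), (1 + 1 + 1 / 2) / 3)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)

  en <- nodal_efficiency(star4)
  expect_equal(en[1], 1)                      # hub reaches all in one hop
  expect_equal(en[2], (1 + 1 / 2 + 1 / 2) / 3)  # leaf
  expect_equal(mean(en), global_efficiency(star4))

  expect_equal(local_efficiency(complete_graph(5))$eloc, 1)
  expect_equal(local_efficiency(star4)$eloc, 0)
  expect_equal(local_efficiency(triangle_pendant)$nodal,
               oracle_local_efficiency(triangle_pendant)$nodal)
})

test_that("betweenness counts shortest-path fractions over unordered pairs", {
  expect_equal(betweenness_centrality(path3), c(0, 1, 0))
  expect_equal(betweenness_centrality(star4), c(3, 0, 0, 0))
  norm <- betweenness_centrality(star4, normalized = TRUE)
  expect_equal(norm[1], 1)
})

test_that("all metrics agree with brute-force oracles on random graphs", {
  set.seed(13)
  for (r in 1:50) {
    n <- sample(4:8, 1)
    adj <- random_graph(n, stats::runif(1, 0.3, 0.8))
    expect_equal(clustering_coef(adj)$ci, oracle_clustering(adj),
                 tolerance = 1e-10)
    expect_equal(distance_matrix(adj), oracle_distances(adj),
                 ignore_attr = TRUE)
    o_pl <- oracle_path_length(adj)
    pl <- suppressWarnings(path_length(adj))
    expect_equal(pl$li, o_pl$li, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(global_efficiency(adj), oracle_global_efficiency(adj),
                 tolerance = 1e-10)
    expect_equal(nodal_efficiency(adj), oracle_nodal_efficiency(adj),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(local_efficiency(adj)$nodal,
                 oracle_local_efficiency(adj)$nodal, tolerance = 1e-10)
    expect_equal(betweenness_centrality(adj), oracle_betweenness(adj),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("degree-preserving rewiring conserves the degree sequence and edges", {
  set.seed(17)
  for (r in 1:25) {
    adj <- random_graph(sample(8:16, 1), 0.4)
    if (sum(adj) / 2 < 2) next
    out <- rewire_degree_preserving(adj, seed = r)
    expect_identical(rowSums(out), rowSums(adj))
    expect_equal(sum(out), sum(adj))
    expect_true(all(diag(out) == 0))
  }
})

test_that("rewired nulls of a lattice-like graph lose clustering", {
  g <- watts_strogatz_graph(90, 10, 0.1, seed = 3)
  cp <- clustering_coef(g)$cp
  null_cp <- vapply(1:20, function(r)
    clustering_coef(rewire_degree_preserving(g, seed = r))$cp, numeric(1))
  expect_lt(mean(null_cp), cp)
})

test_that("a graph that is its own null class scores unit small-world indices", {
  # every double-edge swap on the complete graph is rejected, so the
  # null population equals the graph itself
  k6 <- complete_graph(6)
  sw <- small_world_indices(k6, n_random = 5, seed = 1)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
})

test_that("degree-matched random graphs concentrate near sigma = 1", {
  set.seed(19)
  sigmas <- vapply(1:5, function(r) {
    g <- rewire_degree_preserving(watts_strogatz_graph(90, 10, 1, seed = r),
                                  seed = r)
    small_world_indices(g, n_random = 30, seed = 100 + r)$sigma
  }, numeric(1))
  expect_true(all(sigmas > 0.8 & sigmas < 1.2))
})

test_that("AUC implements the trapezoid formula on the uniform grid", {
  g <- sparsity_grid(0.11, 0.44, 0.01)
  expect_equal(metric_auc(rep(2, length(g)), g), 2 * 0.33)
  expect_equal(metric_auc(g, g), 0.33 * (0.11 + 0.44) / 2)
  expect_equal(metric_auc(c(1, 3), c(0.1, 0.2)), 0.2)
  expect_error(metric_auc(c(1, 2, 3), c(0.1, 0.2, 0.4)), "uniform")

  # linearity: auc(aY + bZ) = a auc(Y) + b auc(Z)
  set.seed(23)
  y <- stats::rnorm(length(g)); z <- stats::rnorm(length(g))
  expect_equal(metric_auc(2 * y - 5 * z, g),
               2 * metric_auc(y, g) - 5 * metric_auc(z, g))
})

test_that("cost efficiency locates the efficiency-minus-cost maximum", {
  g <- sparsity_grid(0.11, 0.44, 0.01)
  ce1 <- cost_efficiency(rep(1, length(g)), g)
  expect_equal(ce1$argmax, 0.11)   # efficiency saturated: cheapest wins

  ce2 <- cost_efficiency(g, g)
  expect_true(all(ce2$difference == 0))
  expect_equal(ce2$argmax, 0.11)
  expect_true(ce2$tie)

  # concave synthetic curve: argmax equals a direct scan
  eglo <- 1 - (g - 0.25)^2 * 4
  ce3 <- cost_efficiency(eglo, g)
  expect_equal(ce3$argmax, g[which.max(eglo - g)])
})
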