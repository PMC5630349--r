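# Synthetic-data generator: ground-truth graphs, time series, motion,
# behaviour, and the assembled two-group study.

test_that("ring lattice has the closed-form clustering and degree structure", {
  g <- watts_strogatz_graph(10, 4, beta = 0)
  expect_equal(sum(g) / 2, 20)
  expect_true(all(rowSums(g) == 4))
  # closed form 3(k-2)/(4(k-1)) for a ring lattice, here 0.5; also
  # verified by the direct neighbour-edge count oracle
  expect_equal(clustering_coef(g)$cp, 0.5)
  expect_equal(clustering_coef(g)$ci, oracle_clustering(g))
})

test_that("rewiring preserves the edge count and simplicity for any beta", {
  for (r in 1:10) {
    beta <- stats::runif(1)
    g <- watts_strogatz_graph(30, 6, beta, seed = r)
    expect_equal(sum(g) / 2, 90)
    expect_true(all(diag(g) == 0))
    expect_true(all(g %in% c(0, 1)))
    expect_identical(g, t(g))
  }
})

test_that("graph generation rejects invalid parameters and is seed-reproducible", {
  expect_error(watts_strogatz_graph(10, 3, 0.1), "even")
  expect_error(watts_strogatz_graph(10, 10, 0.1), "k <")
  expect_error(watts_strogatz_graph(3, 2, 0.1), ">= 4")
  expect_identical(watts_strogatz_graph(40, 6, 0.2, seed = 9),
                   watts_strogatz_graph(40, 6, 0.2, seed = 9))
})

test_that("the Watts-Strogatz regime yields small-world sigma above 1.1", {
  g <- watts_strogatz_graph(90, 10, 0.1, seed = 1)
  sw <- small_world_indices(g, n_random = 100, seed = 1)
  expect_gt(sw$sigma, 1.1)
  expect_gt(sw$gamma, 1)
})

test_that("simulated series realise the target population correlation", {
  # independent channels: off-diagonal sample correlation vanishes
  g0 <- matrix(0, 3, 3)
  ts0 <- simulate_timeseries(g0, 10000, edge_weight = 0, seed = 4)
  r0 <- stats::cor(t(ts0$signal))
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.1)

  # a single edge at weight 0.5: sample r near the analytic population r
  g1 <- rbind(c(0, 1), c(1, 0))
  ts1 <- simulate_timeseries(g1, 10000, edge_weight = 0.5, seed = 5)
  pop_r <- attr(ts1, "population_correlation")[1, 2]
  expect_equal(pop_r, 0.5)  # cov2cor of [[1,.5],[.5,1]]
  expect_lt(abs(stats::cor(ts1$signal[1, ], ts1$signal[2, ]) - pop_r), 0.03)

  # different seeds: different samples, identical population target
  ts2 <- simulate_timeseries(g1, 100, edge_weight = 0.5, seed = 6)
  ts3 <- simulate_timeseries(g1, 100, edge_weight = 0.5, seed = 7)
  expect_false(identical(ts2$signal, ts3$signal))
  expect_identical(attr(ts2, "population_correlation"),
                   attr(ts3, "population_correlation"))
})

test_that("eigenvalue clipping keeps dense targets positive definite", {
  g <- complete_graph(12)
  ts <- simulate_timeseries(g, 50, edge_weight = 0.9, seed = 1)
  pc <- attr(ts, "population_correlation")
  expect_true(all(eigen(pc, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("motion spikes are recovered exactly by downstream scrubbing", {
  m <- simulate_motion(97, spike_frames = c(10, 50), spike_amplitude = 1.0,
                       seed = 2)
  fd <- framewise_displacement(m)
  expect_identical(which(fd > 0.3), c(10L, 50L))

  # zero drift, no spikes: identically zero displacement
  m0 <- simulate_motion(50, drift = 0, seed = 1)
  expect_true(all(framewise_displacement(m0) == 0))

  # sub-threshold spike: nothing to scrub
  m1 <- simulate_motion(97, spike_frames = 5, spike_amplitude = 0.2, seed = 3)
  expect_length(which(framewise_displacement(m1) > 0.3), 0)

  expect_error(simulate_motion(97, spike_frames = 1), "frame 1")
})

test_that("behavioural scores carry the planted linear link", {
  x <- stats::rnorm(18)
  expect_equal(stats::cor(x, simulate_behavior(x, 1, 0, seed = 1)), 1)
  expect_lt(abs(stats::cor(x, simulate_behavior(x, 0, 1, seed = 2))), 0.5)
})

test_that("the planted population correlation is recovered in mean over replicates", {
  # slope/noise chosen for population r = 0.6 at n = 18
  set.seed(10)
  x <- stats::rnorm(18)
  noise <- behavior_noise_for_r(2, stats::sd(x), 0.6)
  r <- vapply(1:500, function(rep)
    stats::cor(x, simulate_behavior(x, 2, noise, seed = rep)), numeric(1))
  expect_lt(abs(mean(r) - 0.6), 0.05)
})

test_that("degrading a single node preserves its degree and the edge count", {
  for (r in 1:20) {
    g <- watts_strogatz_graph(20, 6, 0.1, seed = r)
    gd <- degrade_nodes(g, 7, 1.0, seed = 1000 + r)
    expect_identical(rowSums(gd)[7], rowSums(g)[7])
    expect_equal(sum(gd), sum(g))
    expect_true(all(diag(gd) == 0))
  }
})

test_that("nodal degradation disperses neighbourhoods in expectation", {
  aff <- c(4, 10, 16)
  delta_c <- delta_e <- delta_d <- numeric(200)
  for (r in 1:200) {
    g <- watts_strogatz_graph(20, 6, 0.1, seed = r)
    gd <- degrade_nodes(g, aff, 1.0, seed = 1000 + r)
    expect_equal(sum(gd), sum(g))
    delta_c[r] <- mean(clustering_coef(gd)$ci[aff] - clustering_coef(g)$ci[aff])
    delta_e[r] <- mean(nodal_efficiency(gd)[aff] - nodal_efficiency(g)[aff])
    delta_d[r] <- mean(local_efficiency(gd)$nodal[aff] -
                         local_efficiency(g)$nodal[aff])
  }
  # dispersal of the neighbourhood: clustering and local efficiency drop
  # at the affected nodes in expectation, while the shortcut edges raise
  # their nodal efficiency; degree is invariant by construction
  expect_lt(mean(delta_c), 0)
  expect_lt(mean(delta_d), 0)
  expect_gt(mean(delta_e), 0)
})

test_that("full study generation is reproducible and internally consistent", {
  spec <- ground_truth_spec(n_nodes = 20, n_per_group = 4, n_timepoints = 60,
                            k = 4, affected_nodes = c(3, 11),
                            behavior_node = 3, seed = 21)
  d1 <- simulate_study(spec)
  d2 <- simulate_study(spec)
  expect_identical(d1, d2)
  expect_equal(nrow(d1$subjects), 8)
  expect_identical(d1$subjects$group, rep(c("A", "B"), each = 4))
  expect_length(d1$timeseries, 8)
  expect_true(all(vapply(d1$timeseries, function(ts) ncol(ts$signal),
                         numeric(1)) == 60))
  expect_true(all(vapply(d1$motion, nrow, numeric(1)) == 60))
  expect_identical(names(d1$behavior),
                   c("id", "total", "attention", "motor", "nonplanning"))
})
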