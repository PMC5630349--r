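# Group inference and behaviour correlation.

test_that("pooled t matches the hand formula and base R", {
  tt <- pooled_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(tt$t, 3), -3.674)
  expect_equal(tt$df, 4)

  # cross-check against the independent base-R implementation
  set.seed(31)
  for (r in 1:20) {
    a <- stats::rnorm(sample(3:12, 1)); b <- stats::rnorm(sample(3:12, 1), 0.5)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    mine <- pooled_t_test(a, b)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter))
  }
})

test_that("pooled t is antisymmetric and affine-invariant", {
  set.seed(37)
  a <- stats::rnorm(10); b <- stats::rnorm(12, 1)
  expect_equal(pooled_t_test(a, b)$t, -pooled_t_test(b, a)$t)
  expect_equal(pooled_t_test(3 * a - 7, 3 * b - 7)$t, pooled_t_test(a, b)$t)
  expect_equal(pooled_t_test(a, a)$t, 0)
  expect_equal(pooled_t_test(rep(2, 5), rep(2, 4))$t, 0)
  expect_error(pooled_t_test(rep(1, 5), rep(2, 5)), "zero pooled variance")
})

test_that("summary-statistic t reproduces raw-sample results", {
  set.seed(41)
  a <- stats::rnorm(18); b <- stats::rnorm(18, 0.7)
  raw <- pooled_t_test(a, b)
  summ <- t_test_from_summary(mean(a), stats::sd(a), 18,
                              mean(b), stats::sd(b), 18)
  expect_equal(summ$t, raw$t)
  expect_equal(summ$p, raw$p)
  expect_equal(t_test_from_summary(5, 1, 10, 5, 2, 10)$t, 0)
})

test_that("global curve comparison tests every grid point and the AUC", {
  grid <- sparsity_grid(0.1, 0.3, 0.05)
  set.seed(43)
  ma <- matrix(stats::rnorm(5 * length(grid)), 5)
  curves <- list(cp = ma, eglo = ma + 1)
  res <- compare_global_curves(curves, curves, grid)
  expect_true(all(res$t == 0))
  expect_equal(nrow(res), 2 * (length(grid) + 1))
  expect_equal(sum(is.na(res$sparsity)), 2)  # one AUC row per metric
  expect_error(compare_global_curves(curves, curves, grid[-1]), "grid")
})

test_that("per-sparsity t-tests hold their nominal false-positive rate", {
  set.seed(47)
  grid <- c(0.2, 0.3)
  rej <- vapply(1:200, function(r) {
    ca <- list(m = matrix(stats::rnorm(18 * 2), 18))
    cb <- list(m = matrix(stats::rnorm(18 * 2), 18))
    compare_global_curves(ca, cb, grid)$p[1] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200))
  expect_lt(mean(rej), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

test_that("permutation p matches the exhaustive relabeling oracle at n = 4 + 4", {
  set.seed(53)
  y <- stats::rnorm(8) + rep(c(0, 1), each = 4)
  grp <- rep(c("A", "B"), each = 4)
  yc <- y - mean(y)
  obs <- mean(yc[1:4]) - mean(yc[5:8])
  combos <- utils::combn(8, 4)
  null_diffs <- apply(combos, 2, function(idx)
    mean(yc[idx]) - mean(yc[-idx]))
  p_exact <- mean(abs(null_diffs) >= abs(obs))
  n_perm <- 5000
  p_mc <- permutation_test_nodal(matrix(y, 8, 1), grp, n_perm = n_perm,
                                 seed = 7)$p
  expect_lt(abs(p_mc - p_exact), 2 / sqrt(n_perm))
})

test_that("permutation tests are reproducible, bounded away from 0, and label-destroying", {
  set.seed(59)
  auc <- matrix(stats::rnorm(36 * 4), 36)
  auc[1:18, 2] <- auc[1:18, 2] + 3   # strong planted effect at node 2
  grp <- rep(c("A", "B"), each = 18)
  cov <- cbind(stats::rnorm(36), stats::rnorm(36))
  p1 <- permutation_test_nodal(auc, grp, cov, n_perm = 500, seed = 3)
  p2 <- permutation_test_nodal(auc, grp, cov, n_perm = 500, seed = 3)
  expect_identical(p1, p2)
  expect_true(all(p1$p > 0 & p1$p <= 1))
  expect_equal(p1$p[2], 1 / 501)     # never exactly zero

  # destroying the labels removes the planted effect
  set.seed(61)
  grp_shuffled <- sample(grp)
  p3 <- permutation_test_nodal(auc, grp_shuffled, cov, n_perm = 500, seed = 3)
  expect_gt(p3$p[2], 0.05)
  expect_error(permutation_test_nodal(auc, rep(c("A", "B"), c(2, 34)),
                                      n_perm = 200), "at least 3")
})

test_that("partial correlation reduces to Pearson and removes shared confounds", {
  set.seed(67)
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  pc <- partial_correlation(x, y)
  expect_equal(pc$r, stats::cor(x, y))
  expect_equal(pc$df, 28)

  expect_equal(partial_correlation(x, x, cbind(stats::rnorm(30)))$r, 1)

  # x and y both driven by a covariate: partial r vanishes
  n <- 10000
  c1 <- stats::rnorm(n)
  x2 <- c1 + stats::rnorm(n); y2 <- c1 + stats::rnorm(n)
  expect_gt(stats::cor(x2, y2), 0.3)
  expect_lt(abs(partial_correlation(x2, y2, cbind(c1))$r), 0.1)

  expect_error(partial_correlation(x, y, cbind(x, x)), "collinear")
  expect_warning(out <- partial_correlation(x, rep(1, 30)), "undefined")
  expect_true(is.na(out$r))
})

test_that("the per-node threshold is one over the node count", {
  thr <- per_node_threshold(90)
  expect_equal(thr$exact, 1 / 90)
  expect_equal(thr$rounded, 0.011)
  expect_equal(per_node_threshold(1)$exact, 1)
  expect_equal(per_node_threshold(200)$exact, 0.005)
})

test_that("the behaviour screen flags planted links and reports undefined cases", {
  set.seed(71)
  n <- 36; n_nodes <- 12
  auc <- matrix(stats::rnorm(n * n_nodes), n)
  cov <- cbind(age = stats::rnorm(n), fd = stats::rnorm(n))
  score <- 50 + 5 * auc[, 4] + stats::rnorm(n, 0, 1)  # strong link, node 4
  res <- behavior_screen(list(efficiency = auc),
                         data.frame(total = score), cov)
  hit <- res[res$node == 4, ]
  expect_true(hit$significant)
  expect_gt(hit$r, 0)
  expect_equal(nrow(res), n_nodes)

  # constant score: undefined correlation, flagged not silently zero
  suppressWarnings(
    res2 <- behavior_screen(list(efficiency = auc),
                            data.frame(total = rep(3, n)), cov))
  expect_true(all(is.na(res2$r)))
  expect_true(all(!res2$significant))

  # subsetting restricts to one group
  res3 <- behavior_screen(list(efficiency = auc),
                          data.frame(total = score), cov,
                          subset = 1:18)
  expect_equal(nrow(res3), n_nodes)
})
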