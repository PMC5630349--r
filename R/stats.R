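# Group inference and brain-behaviour correlation: pooled t-tests,
# covariate-adjusted permutation tests on nodal AUCs, and partial
# correlations with behavioural scores.

#' Pooled-variance two-sample t-test
#'
#' Student's two-sample t with the pooled variance estimate,
#' `df = n_a + n_b - 2`, and a two-sided p-value. When both samples
#' have zero variance, equal means give `t = 0` and unequal means are
#' an error (the statistic is undefined).
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `sd_a`,
#'   `sd_b`.
#' @export
#' @examples
#' pooled_t_test(c(1, 2, 3), c(4, 5, 6))$t  # -3.674
pooled_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_input("each sample needs at least 2 observations")
  t_test_from_summary(mean(a), stats::sd(a), length(a),
                      mean(b), stats::sd(b), length(b))
}

#' Pooled t-test from summary statistics
#'
#' The same pooled-variance statistic computed from group means,
#' standard deviations and sizes -- lets printed summary tables be
#' checked without the raw data.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries.
#' @return List with `t`, `df`, `p` and the echoed summaries.
#' @export
#' @examples
#' t_test_from_summary(76.06, 8.26, 18, 64.89, 11.14, 18)$t  # 3.417
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop_input("each group needs n >= 2")
  if (sd_a < 0 || sd_b < 0) stop_input("standard deviations must be >= 0")
  df <- n_a + n_b - 2
  pooled_var <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(pooled_var * (1 / n_a + 1 / n_b))
  if (se == 0) {
    if (mean_a == mean_b) {
      t <- 0
    } else {
      stop_input("zero pooled variance with unequal means: t undefined")
    }
  } else {
    t <- (mean_a - mean_b) / se
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_a = mean_a, mean_b = mean_b, sd_a = sd_a, sd_b = sd_b,
       n_a = n_a, n_b = n_b)
}

#' Per-sparsity and AUC group comparison of global metric curves
#'
#' Pooled two-sample t-tests at every grid point of each global-metric
#' curve, plus one test on each metric's AUC. No multiplicity
#' correction is applied.
#'
#' @param curves_a,curves_b lists (one element per metric) of matrices
#'   with subjects in rows and grid points in columns; both groups must
#'   share metric names and grid.
#' @param grid the sparsity grid (columns of the matrices).
#' @return Data frame with columns `metric`, `sparsity` (`NA` for the
#'   AUC row), `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
compare_global_curves <- function(curves_a, curves_b, grid) {
  if (!identical(sort(names(curves_a)), sort(names(curves_b))))
    stop_input("the two groups carry different metric sets")
  out <- list()
  for (metric in names(curves_a)) {
    ma <- as.matrix(curves_a[[metric]])
    mb <- as.matrix(curves_b[[metric]])
    if (ncol(ma) != length(grid) || ncol(mb) != length(grid))
      stop_input(sprintf("grid mismatch for metric '%s'", metric))
    rows <- lapply(seq_along(grid), function(k) {
      tt <- pooled_t_test(ma[, k], mb[, k])
      data.frame(metric = metric, sparsity = grid[k], t = tt$t,
                 df = tt$df, p = tt$p, mean_a = tt$mean_a,
                 mean_b = tt$mean_b)
    })
    auc_a <- apply(ma, 1, metric_auc, grid = grid)
    auc_b <- apply(mb, 1, metric_auc, grid = grid)
    tt <- pooled_t_test(auc_a, auc_b)
    rows <- c(rows, list(data.frame(metric = metric, sparsity = NA_real_,
                                    t = tt$t, df = tt$df, p = tt$p,
                                    mean_a = tt$mean_a, mean_b = tt$mean_b)))
    out[[metric]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Residualize the columns of y against [intercept | covariates].
residualize <- function(y, covariates = NULL) {
  y <- as.matrix(y)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(sweep(y, 2, colMeans(y)))
  }
  x <- cbind(1, as.matrix(covariates))
  qrx <- qr(x)
  if (qrx$rank < ncol(x))
    stop_input("collinear covariates: design matrix is rank deficient")
  qr.resid(qrx, y)
}

#' Covariate-adjusted permutation test on nodal AUC values
#'
#' Tests, for each node, the group difference in an AUC summary while
#' controlling for covariates. Covariates are regressed out of every
#' node's AUC across all subjects; the observed absolute difference of
#' group means of the residuals is then compared against its null
#' distribution over `n_perm` random relabelings preserving the group
#' sizes. The p-value uses the add-one convention
#' `(1 + #{null >= observed}) / (1 + n_perm)`, so it is never exactly 0.
#'
#' @param auc numeric matrix, subjects in rows, nodes in columns.
#' @param group factor or character vector of two group labels aligned
#'   with the rows.
#' @param covariates optional numeric matrix (e.g. age and mean FD),
#'   rows aligned with subjects.
#' @param n_perm number of permutations (default 5000).
#' @param seed optional integer seed (runs are bit-reproducible).
#' @return Data frame with one row per node: `node`, `observed`
#'   (signed difference of residual group means, first level minus
#'   second), `p`.
#' @export
permutation_test_nodal <- function(auc, group, covariates = NULL,
                                   n_perm = 5000, seed = NULL) {
  auc <- as.matrix(auc)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop_input("group must have exactly 2 levels")
  if (length(group) != nrow(auc))
    stop_input("group labels and AUC rows differ in length")
  if (!is.null(covariates) && NROW(covariates) != nrow(auc))
    stop_input("covariate rows and AUC rows differ")
  if (min(table(group)) < 3) stop_input("each group needs at least 3 subjects")
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
  res <- residualize(auc, covariates)
  ia <- group == levels(group)[1]
  observed <- colMeans(res[ia, , drop = FALSE]) -
    colMeans(res[!ia, , drop = FALSE])
  n <- nrow(res)
  n_a <- sum(ia)
  exceed <- local_seed(seed, {
    cnt <- numeric(ncol(res))
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n, n_a)
      null_diff <- colMeans(res[idx, , drop = FALSE]) -
        colMeans(res[-idx, , drop = FALSE])
      cnt <- cnt + (abs(null_diff) >= abs(observed))
    }
    cnt
  })
  data.frame(node = seq_len(ncol(auc)), observed = as.numeric(observed),
             p = (1 + exceed) / (1 + n_perm))
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' least-squares removal of an intercept and the covariate columns;
#' the p-value uses the t transform with `df = n - 2 - n_covariates`.
#' With no covariates this is exactly the Pearson correlation. Zero
#' residual variance in either variable is reported as undefined
#' (`r = NA`) rather than propagated.
#'
#' @param x,y numeric vectors, one value per subject.
#' @param covariates optional numeric matrix with rows aligned to the
#'   subjects.
#' @return List with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop_input("x and y lengths differ")
  k <- if (is.null(covariates)) 0 else NCOL(covariates)
  if (n <= k + 2)
    stop_input("need more subjects than covariates + 2")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  degenerate <- function(res, orig)
    stats::sd(orig) == 0 || stats::sd(res) <= 1e-12 * max(1, stats::sd(orig))
  if (degenerate(rx, x) || degenerate(ry, y)) {
    warning("zero residual variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, df = n - 2 - k, n = n))
  }
  r <- as.numeric(stats::cor(rx, ry))
  df <- n - 2 - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df, n = n)
}

#' Per-node significance threshold
#'
#' The false-positive correction used for nodal correlation screens:
#' one divided by the number of network nodes (0.011 for a 90-node
#' parcellation). Returned exactly, with the conventional 3-decimal
#' rounding alongside.
#'
#' @param n_nodes number of nodes (>= 1).
#' @return List with `exact` (`1/n_nodes`) and `rounded` (3 decimals).
#' @export
#' @examples
#' per_node_threshold(90)  # exact 0.0111..., rounded 0.011
per_node_threshold <- function(n_nodes) {
  if (!is_count(n_nodes) || n_nodes < 1) stop_input("n_nodes must be >= 1")
  list(exact = 1 / n_nodes, rounded = round(1 / n_nodes, 3))
}

#' Screen nodal AUCs against behavioural scores
#'
#' Partial correlation (controlling for the supplied covariates) of
#' every (node, nodal metric) AUC against every behavioural score,
#' either across all subjects or within one group. Each row is flagged
#' at the per-node threshold `1/N` and at the conventional 0.05 level.
#' Subjects with missing scores are dropped with a message.
#'
#' @param nodal_aucs named list of AUC matrices (subjects x nodes), one
#'   per nodal metric.
#' @param scores data frame of behavioural scores (subjects in rows).
#' @param covariates numeric matrix aligned with subjects, or `NULL`.
#' @param subset optional logical/integer index restricting the screen
#'   to one group of subjects.
#' @return Data frame: `metric`, `node`, `score`, `r`, `p`,
#'   `significant` (p < 1/N), `nominal` (p < 0.05).
#' @export
behavior_screen <- function(nodal_aucs, scores, covariates = NULL,
                            subset = NULL) {
  stopifnot(is.list(nodal_aucs), length(nodal_aucs) >= 1)
  scores <- as.data.frame(scores)
  n_nodes <- ncol(as.matrix(nodal_aucs[[1]]))
  thr <- per_node_threshold(n_nodes)$exact
  if (!is.null(subset)) {
    scores <- scores[subset, , drop = FALSE]
    nodal_aucs <- lapply(nodal_aucs, function(m)
      as.matrix(m)[subset, , drop = FALSE])
    if (!is.null(covariates))
      covariates <- as.matrix(covariates)[subset, , drop = FALSE]
  }
  complete <- stats::complete.cases(scores)
  if (any(!complete)) {
    message(sprintf("dropping %d subject(s) with missing scores",
                    sum(!complete)))
    scores <- scores[complete, , drop = FALSE]
    nodal_aucs <- lapply(nodal_aucs, function(m)
      as.matrix(m)[complete, , drop = FALSE])
    if (!is.null(covariates))
      covariates <- as.matrix(covariates)[complete, , drop = FALSE]
  }
  rows <- list()
  for (metric in names(nodal_aucs)) {
    m <- as.matrix(nodal_aucs[[metric]])
    for (score_name in names(scores)) {
      for (node in seq_len(ncol(m))) {
        pc <- partial_correlation(m[, node], scores[[score_name]],
                                  covariates)
        rows[[length(rows) + 1]] <- data.frame(
          metric = metric, node = node, score = score_name,
          r = pc$r, p = pc$p,
          significant = !is.na(pc$p) && pc$p < thr,
          nominal = !is.na(pc$p) && pc$p < 0.05)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
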