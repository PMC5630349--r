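# End-to-end analysis: preprocessing -> connectivity -> sparsity-grid
# graph metrics -> group inference and behaviour correlation, returned
# as a single classed object with print/summary/plot methods.

#' Analyse a two-group connectome study
#'
#' Runs the full pipeline on a dataset (from [simulate_study] or
#' [read_study]): per-subject preprocessing (detrend, ideal bandpass,
#' motion nuisance regression, framewise-displacement scrubbing),
#' Fisher-z Pearson connectivity, binarization across the sparsity
#' grid, global metrics (`C_p`, `L_p`, `E_glo`, `E_loc`, and with
#' `n_random > 0` the small-world indices gamma/lambda/sigma against
#' degree-preserving nulls), nodal metrics (degree, nodal efficiency,
#' betweenness), AUC summaries, per-sparsity pooled t-tests on the
#' global curves, covariate-adjusted permutation tests on the nodal
#' AUCs, and a partial-correlation screen of nodal AUCs against the
#' behavioural scores (across all subjects and within the second
#' group), controlling age and mean framewise displacement.
#'
#' @param dataset a `connectome_dataset`.
#' @param grid sparsity grid (default 0.11-0.44 step 0.01).
#' @param n_drop initial volumes to discard (default 0: the synthetic
#'   generator emits post-equilibrium frames only).
#' @param low_hz,high_hz bandpass edges.
#' @param fd_threshold scrubbing threshold in mm.
#' @param n_random null networks per graph for the small-world indices
#'   (0 skips them and the sigma/gamma/lambda curves).
#' @param n_perm permutations for the nodal tests.
#' @param seed integer seed governing nulls and permutations.
#' @param verbose print progress?
#' @return An object of class `connectome_study`; see Details.
#' @details The returned object carries `qc` (per-subject mean FD and
#'   scrubbed-frame counts), `global_curves` (per-group lists of
#'   subject x grid matrices per metric), `global_auc` (per-subject
#'   AUC of each global metric), `nodal_auc` (per-metric subject x
#'   node AUC matrices), `global_tests`, `nodal_tests`,
#'   `cost_efficiency`, `behavior_all`, `behavior_group_b` and `log`.
#' @export
#' @examples
#' \donttest{
#' spec <- ground_truth_spec(n_nodes = 20, n_per_group = 5,
#'                           n_timepoints = 80, k = 4, seed = 3)
#' fit <- connectome_study(simulate_study(spec),
#'                         grid = sparsity_grid(0.15, 0.30, 0.05),
#'                         n_random = 5, n_perm = 200, seed = 3)
#' summary(fit)
#' }
connectome_study <- function(dataset,
                             grid = sparsity_grid(),
                             n_drop = 0,
                             low_hz = 0.01, high_hz = 0.10,
                             fd_threshold = 0.3,
                             n_random = 100,
                             n_perm = 5000,
                             seed = 1,
                             verbose = FALSE) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  subjects <- dataset$subjects
  n_sub <- nrow(subjects)
  groups <- subjects$group
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop_input("dataset must contain exactly 2 groups")
  note <- function(...) if (verbose) message(sprintf(...))

  # --- preprocessing -------------------------------------------------
  qc <- data.frame(id = subjects$id, group = groups,
                   mean_fd = NA_real_, n_scrubbed = NA_integer_,
                   n_frames = NA_integer_)
  clean <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    id <- subjects$id[s]
    out <- tryCatch(
      preprocess_subject(dataset$timeseries[[id]],
                         motion = dataset$motion[[id]],
                         n_drop = n_drop, low_hz = low_hz,
                         high_hz = high_hz, fd_threshold = fd_threshold),
      error = function(e) stop_input(sprintf("prep stage, subject %s: %s",
                                             id, conditionMessage(e))))
    clean[[s]] <- out
    q <- attr(out, "qc")
    qc$mean_fd[s] <- q$mean_fd
    qc$n_scrubbed[s] <- q$n_scrubbed
    qc$n_frames[s] <- q$n_frames
  }
  note("preprocessed %d subjects", n_sub)

  # --- connectivity and grid metrics --------------------------------
  n_nodes <- nrow(clean[[1]]$signal)
  g_names <- c("cp", "lp", "eglo", "eloc")
  if (n_random > 0) g_names <- c(g_names, "gamma", "lambda", "sigma")
  n_metrics <- c("degree", "efficiency", "betweenness")
  n_grid <- length(grid)
  global_curves <- lapply(stats::setNames(g_names, g_names), function(m)
    matrix(NA_real_, n_sub, n_grid,
           dimnames = list(subjects$id, grid)))
  nodal_curves <- lapply(stats::setNames(n_metrics, n_metrics), function(m)
    array(NA_real_, c(n_sub, n_nodes, n_grid)))
  for (s in seq_len(n_sub)) {
    id <- subjects$id[s]
    z <- tryCatch(connectivity_matrix(clean[[s]]),
                  error = function(e)
                    stop_input(sprintf("netcon stage, subject %s: %s", id,
                                       conditionMessage(e))))
    for (k in seq_len(n_grid)) {
      adj <- binarize_at_sparsity(z, grid[k])
      gm <- global_metrics(adj, n_random = n_random,
                           seed = derive_seed(seed, 11L, s, k))
      for (m in intersect(g_names, names(gm)))
        global_curves[[m]][s, k] <- gm[[m]]
      d <- distance_matrix(adj)
      nodal_curves$degree[s, , k] <- rowSums(adj)
      nodal_curves$efficiency[s, , k] <- nodal_efficiency(adj, dist_mat = d)
      nodal_curves$betweenness[s, , k] <- betweenness_centrality(adj)
    }
    note("metrics done for subject %s (%d/%d)", id, s, n_sub)
  }

  # --- AUC summaries -------------------------------------------------
  global_auc <- vapply(global_curves, function(m)
    apply(m, 1, metric_auc, grid = grid),
    numeric(n_sub))
  nodal_auc <- lapply(nodal_curves, function(a) {
    out <- apply(a, c(1, 2), metric_auc, grid = grid)
    dimnames(out) <- list(subjects$id, NULL)
    out
  })

  # --- group inference ----------------------------------------------
  ia <- groups == lv[1]
  split_curves <- function(keep)
    lapply(global_curves, function(m) m[keep, , drop = FALSE])
  global_tests <- compare_global_curves(split_curves(ia), split_curves(!ia),
                                        grid)
  covariates <- cbind(age = subjects$age, mean_fd = qc$mean_fd)
  nodal_tests <- lapply(stats::setNames(n_metrics, n_metrics), function(m)
    permutation_test_nodal(nodal_auc[[m]], groups, covariates,
                           n_perm = n_perm,
                           seed = derive_seed(seed, 21L, match(m, n_metrics))))

  # --- cost efficiency ----------------------------------------------
  ce <- lapply(stats::setNames(lv, lv), function(g)
    cost_efficiency(colMeans(global_curves$eglo[groups == g, , drop = FALSE]),
                    grid))

  # --- behaviour ----------------------------------------------------
  behavior_all <- behavior_group_b <- NULL
  if (!is.null(dataset$behavior) && ncol(dataset$behavior) > 1) {
    scores <- dataset$behavior[, setdiff(names(dataset$behavior), "id"),
                               drop = FALSE]
    behavior_all <- behavior_screen(nodal_auc, scores, covariates)
    behavior_group_b <- behavior_screen(nodal_auc, scores, covariates,
                                        subset = groups == lv[2])
  }

  structure(
    list(subjects = subjects, groups = lv, grid = grid, qc = qc,
         global_curves = global_curves, global_auc = global_auc,
         nodal_auc = nodal_auc, global_tests = global_tests,
         nodal_tests = nodal_tests, cost_efficiency = ce,
         behavior_all = behavior_all, behavior_group_b = behavior_group_b,
         log = list(seed = seed, n_random = n_random, n_perm = n_perm,
                    fd_threshold = fd_threshold, n_drop = n_drop,
                    band = c(low_hz, high_hz), grid = grid,
                    n_scrubbed_total = sum(qc$n_scrubbed),
                    per_node_threshold = per_node_threshold(n_nodes))),
    class = "connectome_study"
  )
}

#' @export
print.connectome_study <- function(x, ...) {
  cat(sprintf(
    "Connectome study: %d subjects (%s = %d, %s = %d), %d nodes, grid %g-%g\n",
    nrow(x$subjects), x$groups[1], sum(x$subjects$group == x$groups[1]),
    x$groups[2], sum(x$subjects$group == x$groups[2]),
    ncol(x$nodal_auc[[1]]), min(x$grid), max(x$grid)))
  cat(sprintf("  seed %d, %d nulls/graph, %d permutations\n",
              x$log$seed, x$log$n_random, x$log$n_perm))
  invisible(x)
}

#' @export
summary.connectome_study <- function(object, alpha = 0.05, ...) {
  x <- object
  cat("Quality control\n")
  cat(sprintf("  mean FD: %.3f mm (range %.3f-%.3f); %d frames scrubbed in total\n",
              mean(x$qc$mean_fd), min(x$qc$mean_fd), max(x$qc$mean_fd),
              x$log$n_scrubbed_total))
  auc_rows <- x$global_tests[is.na(x$global_tests$sparsity), ]
  cat("\nGlobal metric AUC comparisons (pooled t)\n")
  for (i in seq_len(nrow(auc_rows)))
    cat(sprintf("  %-7s t = %6.3f  p = %.4f\n", auc_rows$metric[i],
                auc_rows$t[i], auc_rows$p[i]))
  cat("\nNodal permutation tests (covariate-adjusted)\n")
  for (m in names(x$nodal_tests)) {
    sig <- x$nodal_tests[[m]]$node[x$nodal_tests[[m]]$p < alpha]
    cat(sprintf("  %-12s %d node(s) with p < %.2f%s\n", m, length(sig),
                alpha,
                if (length(sig)) paste0(": ",
                  paste(utils::head(sig, 12), collapse = ", ")) else ""))
  }
  if (!is.null(x$behavior_all)) {
    thr <- x$log$per_node_threshold$exact
    sig <- x$behavior_all[x$behavior_all$significant, ]
    cat(sprintf("\nBehaviour screen (all subjects): %d pair(s) below 1/N = %.3f\n",
                nrow(sig), thr))
    if (nrow(sig))
      for (i in seq_len(min(nrow(sig), 10)))
        cat(sprintf("  %s node %d ~ %s: r = %.3f, p = %.4f\n",
                    sig$metric[i], sig$node[i], sig$score[i], sig$r[i],
                    sig$p[i]))
  }
  invisible(x)
}

#' Plot global metric curves of a fitted study
#'
#' Group-mean curves of each global metric across the sparsity grid
#' (one panel per metric), plus the cost-efficiency curve with its
#' maximum marked.
#'
#' @param x a `connectome_study`.
#' @param metrics which global metrics to draw.
#' @param ... passed to [graphics::matplot].
#' @return `x`, invisibly.
#' @export
plot.connectome_study <- function(x, metrics = names(x$global_curves), ...) {
  metrics <- intersect(metrics, names(x$global_curves))
  n_panel <- length(metrics) + 1
  old <- graphics::par(mfrow = c(ceiling(n_panel / 2), 2),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  groups <- x$subjects$group
  for (m in metrics) {
    means <- sapply(x$groups, function(g)
      colMeans(x$global_curves[[m]][groups == g, , drop = FALSE]))
    graphics::matplot(x$grid, means, type = "l", lty = 1, lwd = 2,
                      col = c("steelblue", "firebrick"),
                      xlab = "sparsity", ylab = m, main = m, ...)
    graphics::legend("topleft", legend = x$groups, bty = "n",
                     col = c("steelblue", "firebrick"), lty = 1, lwd = 2)
  }
  ce <- x$cost_efficiency[[1]]
  graphics::plot(x$grid, ce$difference, type = "l", lwd = 2,
                 xlab = "sparsity (cost)", ylab = "E_glo - cost",
                 main = "cost efficiency")
  graphics::abline(v = ce$argmax, lty = 2)
  invisible(x)
}
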