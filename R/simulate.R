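# Synthetic two-group study generator. Produces small-world ground-truth
# graphs, correlated Gaussian regional time series, rigid-body motion
# traces with controllable spikes, and behavioural scores linked to a
# nodal graph property -- so that every downstream stage of the pipeline
# has a recoverable target.

#' Generate a Watts-Strogatz small-world graph
#'
#' Builds a ring lattice on `n_nodes` nodes where each node is joined to
#' its `k` nearest neighbours, then rewires the far endpoint of each
#' lattice edge with probability `beta` to a uniformly chosen
#' non-neighbour. Rewiring moves endpoints but never deletes edges, so
#' the edge count is `n_nodes * k / 2` for every `beta`; at `beta = 0`
#' every node has degree exactly `k`.
#'
#' @param n_nodes number of nodes (>= 4).
#' @param k even neighbourhood size, `2 <= k < n_nodes`.
#' @param beta rewiring probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
#' @examples
#' adj <- watts_strogatz_graph(90, 10, 0.1, seed = 1)
#' sum(adj) / 2  # 450 edges
watts_strogatz_graph <- function(n_nodes, k, beta, seed = NULL) {
  if (!is_count(n_nodes) || n_nodes < 4)
    stop_input("n_nodes must be an integer >= 4")
  if (!is_count(k) || k %% 2 != 0 || k < 2 || k >= n_nodes)
    stop_input("k must be even with 2 <= k < n_nodes")
  if (!is.numeric(beta) || beta < 0 || beta > 1)
    stop_input("beta must be a probability in [0, 1]")
  local_seed(seed, {
    n <- n_nodes
    adj <- matrix(0, n, n)
    half <- k / 2
    for (j in seq_len(half)) {
      idx <- seq_len(n)
      tgt <- (idx + j - 1) %% n + 1
      adj[cbind(idx, tgt)] <- 1
      adj[cbind(tgt, idx)] <- 1
    }
    if (beta > 0) {
      for (j in seq_len(half)) {
        for (i in seq_len(n)) {
          tgt <- (i + j - 1) %% n + 1
          if (adj[i, tgt] == 1 && stats::runif(1) < beta) {
            candidates <- which(adj[i, ] == 0)
            candidates <- setdiff(candidates, i)
            if (length(candidates) == 0) next  # node saturated
            w <- candidates[sample.int(length(candidates), 1)]
            adj[i, tgt] <- adj[tgt, i] <- 0
            adj[i, w] <- adj[w, i] <- 1
          }
        }
      }
    }
    adj
  })
}

#' Degrade the connectivity of selected nodes
#'
#' For each affected node, a fraction of its edges is rewired to
#' uniformly chosen current non-neighbours. The affected node keeps its
#' degree and the global edge count is unchanged; its former partners
#' lose an edge. This disperses a node's neighbourhood -- lowering its
#' local clustering while leaving its degree intact -- and is the
#' planted group-level lesion of the synthetic study.
#'
#' @param adj binary adjacency matrix.
#' @param nodes integer indices of affected nodes.
#' @param fraction proportion of each affected node's edges to rewire,
#'   in `[0, 1]`.
#' @param seed optional integer seed.
#' @return Degraded adjacency matrix.
#' @export
degrade_nodes <- function(adj, nodes, fraction, seed = NULL) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  if (length(nodes) && (any(nodes < 1) || any(nodes > n)))
    stop_input("affected nodes must lie in [1, n_nodes]")
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop_input("fraction must lie in [0, 1]")
  local_seed(seed, {
    for (a in nodes) {
      nbrs <- which(adj[a, ] == 1)
      n_move <- round(fraction * length(nbrs))
      if (n_move == 0) next
      move <- nbrs[sample.int(length(nbrs), n_move)]
      for (b in move) {
        candidates <- setdiff(which(adj[a, ] == 0), a)
        if (length(candidates) == 0) next
        w <- candidates[sample.int(length(candidates), 1)]
        adj[a, b] <- adj[b, a] <- 0
        adj[a, w] <- adj[w, a] <- 1
      }
    }
    adj
  })
}

#' Simulate regional time series from a ground-truth graph
#'
#' Draws a zero-mean multichannel Gaussian series whose population
#' covariance is `noise_sd^2 * I + edge_weight * A`: adjacent node pairs
#' are correlated at `edge_weight / noise_sd^2`, non-adjacent pairs are
#' uncorrelated. If the target matrix is not positive definite its
#' eigenvalues are clipped at `1e-6` before sampling; the population
#' correlation actually realised (after any clipping) is returned in the
#' `population_correlation` attribute.
#'
#' @param adj binary adjacency matrix.
#' @param n_timepoints number of time frames.
#' @param edge_weight covariance placed on adjacent pairs.
#' @param noise_sd per-channel noise standard deviation (> 0).
#' @param tr sampling interval in seconds.
#' @param seed optional integer seed.
#' @param id subject identifier.
#' @return An [roi_ts] object with attribute `population_correlation`.
#' @export
simulate_timeseries <- function(adj, n_timepoints, edge_weight = 0.4,
                                noise_sd = 1, tr = 3, seed = NULL,
                                id = "subject") {
  adj <- check_adjacency(adj)
  if (!is_count(n_timepoints) || n_timepoints < 2)
    stop_input("n_timepoints must be an integer >= 2")
  if (noise_sd <= 0) stop_input("noise_sd must be positive")
  n <- nrow(adj)
  sigma <- noise_sd^2 * diag(n) + edge_weight * adj
  eig <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(eig$values, 1e-6)
  if (min(lam) <= 0)
    stop_input(sprintf(
      "target covariance not positive definite after projection (min eigenvalue %g)",
      min(lam)))
  sigma_pd <- eig$vectors %*% (lam * t(eig$vectors))
  pop_cor <- stats::cov2cor(sigma_pd)
  x <- local_seed(seed, {
    z <- matrix(stats::rnorm(n * n_timepoints), n, n_timepoints)
    eig$vectors %*% (sqrt(lam) * (t(eig$vectors) %*% z))
  })
  ts <- roi_ts(x, tr = tr, id = id)
  attr(ts, "population_correlation") <- pop_cor
  ts
}

#' Simulate a rigid-body motion trace
#'
#' Produces six motion-parameter columns (x, y, z translations in mm;
#' pitch, roll, yaw rotations in degrees) as slow random-walk drift,
#' plus persistent step displacements of `spike_amplitude` mm in the x
#' translation at the requested frames. Framewise displacement computed
#' downstream then exceeds a scrubbing threshold exactly at the spike
#' frames whenever the amplitude clears the threshold and the drift
#' stays below it.
#'
#' @param n_timepoints number of frames.
#' @param spike_frames integer frame indices (1-based, >= 2) receiving a
#'   step displacement; frame 1 is disallowed because framewise
#'   displacement is undefined there.
#' @param spike_amplitude step size in mm.
#' @param drift maximum per-frame random-walk increment for each
#'   parameter (mm or degrees). The default keeps the per-frame
#'   framewise displacement of the baseline below ~0.05 mm.
#' @param seed optional integer seed.
#' @return Numeric matrix `n_timepoints x 6` with columns
#'   `x, y, z, pitch, roll, yaw`.
#' @export
simulate_motion <- function(n_timepoints, spike_frames = integer(0),
                            spike_amplitude = 1.0, drift = 0.008,
                            seed = NULL) {
  if (!is_count(n_timepoints) || n_timepoints < 2)
    stop_input("n_timepoints must be an integer >= 2")
  if (length(spike_frames)) {
    if (any(spike_frames < 2) || any(spike_frames > n_timepoints))
      stop_input("spike frames must lie in [2, n_timepoints]; framewise displacement is undefined at frame 1")
  }
  local_seed(seed, {
    steps <- matrix(stats::runif(n_timepoints * 6, -drift, drift),
                    n_timepoints, 6)
    steps[1, ] <- 0
    m <- apply(steps, 2, cumsum)
    for (f in spike_frames) {
      m[f:n_timepoints, 1] <- m[f:n_timepoints, 1] + spike_amplitude
    }
    colnames(m) <- c("x", "y", "z", "pitch", "roll", "yaw")
    m
  })
}

#' Simulate behavioural scores linked to a nodal property
#'
#' Generates `intercept + slope * nodal_values + N(0, noise_sd^2)` per
#' subject. With `x = nodal_values`, the population correlation between
#' score and nodal value is
#' `slope * sd(x) / sqrt(slope^2 * var(x) + noise_sd^2)`.
#'
#' @param nodal_values per-subject values of the chosen nodal property.
#' @param slope linear coefficient.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param intercept baseline score.
#' @param seed optional integer seed.
#' @return Numeric score vector, one value per subject.
#' @export
simulate_behavior <- function(nodal_values, slope, noise_sd,
                              intercept = 60, seed = NULL) {
  if (!is.numeric(nodal_values)) stop_input("nodal_values must be numeric")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_input("noise_sd must be >= 0")
  local_seed(seed, {
    intercept + slope * nodal_values +
      stats::rnorm(length(nodal_values), 0, noise_sd)
  })
}

#' Noise level that plants a target behaviour-topology correlation
#'
#' Given the spread of the nodal property across subjects and a slope,
#' returns the Gaussian noise standard deviation at which the population
#' correlation between score and nodal value equals `target_r`.
#'
#' @param slope linear coefficient of the behavioural link.
#' @param sd_x standard deviation of the nodal property across subjects.
#' @param target_r desired population correlation, `0 < |target_r| <= 1`.
#' @return Noise standard deviation.
#' @export
behavior_noise_for_r <- function(slope, sd_x, target_r) {
  if (target_r == 0 || abs(target_r) > 1)
    stop_input("target_r must satisfy 0 < |target_r| <= 1")
  abs(slope) * sd_x * sqrt(1 / target_r^2 - 1)
}

#' Ground-truth specification for a synthetic two-group study
#'
#' Collects every knob of the generator: cohort and acquisition sizes,
#' the Watts-Strogatz base graph, the planted group-B nodal lesion, the
#' time-series signal model, motion-spike behaviour and the behavioural
#' link. Defaults emulate the reference study design: two groups of 18
#' subjects, 90 regions, 97 frames at TR = 3 s.
#'
#' @param n_nodes number of network nodes.
#' @param n_per_group subjects per group.
#' @param n_timepoints frames per subject.
#' @param tr_seconds sampling interval.
#' @param k,beta Watts-Strogatz lattice neighbourhood and rewiring
#'   probability of the base graph.
#' @param affected_nodes node indices degraded in group B.
#' @param degradation_fraction fraction of each affected node's edges
#'   rewired in group B.
#' @param edge_weight,noise_sd time-series signal model (see
#'   [simulate_timeseries]).
#' @param spike_prob probability a subject has motion spikes.
#' @param max_spikes maximum number of spike frames per spiking subject.
#' @param spike_amplitude spike step in mm.
#' @param behavior_node node whose true nodal efficiency drives the
#'   behavioural score (defaults to the first affected node).
#' @param behavior_slope linear coefficient of the behavioural link.
#' @param behavior_r target population correlation between score and
#'   nodal property; sets the noise level via [behavior_noise_for_r].
#' @param seed master integer seed; every stage derives its own stream
#'   from it via [derive_seed].
#' @return An object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(n_nodes = 90, n_per_group = 18,
                              n_timepoints = 97, tr_seconds = 3,
                              k = 10, beta = 0.1,
                              affected_nodes = c(10, 25, 40, 55, 70, 85),
                              degradation_fraction = 0.5,
                              edge_weight = 0.4, noise_sd = 1,
                              spike_prob = 0.5, max_spikes = 3,
                              spike_amplitude = 1.0,
                              behavior_node = NULL,
                              behavior_slope = 40,
                              behavior_r = 0.6,
                              seed = 1) {
  if (!is_count(n_nodes) || n_nodes < 4) stop_input("n_nodes must be >= 4")
  if (beta < 0 || beta > 1) stop_input("beta must lie in [0, 1]")
  if (degradation_fraction < 0 || degradation_fraction > 1)
    stop_input("degradation_fraction must lie in [0, 1]")
  affected_nodes <- as.integer(affected_nodes)
  if (length(affected_nodes) &&
      (any(affected_nodes < 1) || any(affected_nodes > n_nodes)))
    stop_input("affected_nodes must lie in [1, n_nodes]")
  if (is.null(behavior_node))
    behavior_node <- if (length(affected_nodes)) affected_nodes[1] else 1L
  structure(
    list(n_nodes = n_nodes, n_per_group = n_per_group,
         n_timepoints = n_timepoints, tr_seconds = tr_seconds,
         k = k, beta = beta, affected_nodes = affected_nodes,
         degradation_fraction = degradation_fraction,
         edge_weight = edge_weight, noise_sd = noise_sd,
         spike_prob = spike_prob, max_spikes = max_spikes,
         spike_amplitude = spike_amplitude,
         behavior_node = as.integer(behavior_node),
         behavior_slope = behavior_slope, behavior_r = behavior_r,
         seed = as.integer(seed)),
    class = "ground_truth_spec"
  )
}

#' @export
print.ground_truth_spec <- function(x, ...) {
  cat(sprintf(
    paste0("Synthetic study spec: 2 x %d subjects, %d nodes, %d frames ",
           "(TR = %g s)\n  base graph: Watts-Strogatz k = %d, beta = %g\n",
           "  group-B lesion: %d nodes, fraction %g\n",
           "  behavioural link: node %d, target r = %g\n  seed: %d\n"),
    x$n_per_group, x$n_nodes, x$n_timepoints, x$tr_seconds, x$k, x$beta,
    length(x$affected_nodes), x$degradation_fraction,
    x$behavior_node, x$behavior_r, x$seed
  ))
  invisible(x)
}

# Stage tags of the seed-splitting scheme (documented so any stage can
# be regenerated in isolation).
.stage <- c(graph = 1L, timeseries = 2L, motion = 3L, behavior = 4L,
            age = 5L)

#' Simulate a complete synthetic two-group study
#'
#' Generates, for each subject: a ground-truth graph (group A: the
#' Watts-Strogatz base; group B: the same construction with the
#' specified nodes degraded), a regional time series realised from that
#' graph, a motion trace with randomly placed spikes, an age, and
#' behavioural scores (total plus attentional, motor and non-planning
#' subscales) linearly linked to the true nodal efficiency of the
#' behaviour node. All randomness derives from the spec's master seed,
#' with one sub-stream per (stage, subject).
#'
#' @param spec a [ground_truth_spec].
#' @return An object of class `connectome_dataset` with elements
#'   `subjects` (data frame: id, group, age), `timeseries`, `motion`,
#'   `true_graphs` (named lists), `behavior` (data frame of scores) and
#'   `spec`.
#' @export
#' @examples
#' spec <- ground_truth_spec(n_nodes = 20, n_per_group = 4,
#'                           n_timepoints = 60, k = 4, seed = 7)
#' dat <- simulate_study(spec)
#' dat$subjects
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  n_sub <- 2 * spec$n_per_group
  ids <- sprintf("sub%02d", seq_len(n_sub))
  group <- rep(c("A", "B"), each = spec$n_per_group)

  true_graphs <- vector("list", n_sub)
  timeseries <- vector("list", n_sub)
  motion <- vector("list", n_sub)
  enodal_behavior <- numeric(n_sub)

  for (s in seq_len(n_sub)) {
    g <- watts_strogatz_graph(spec$n_nodes, spec$k, spec$beta,
                              seed = derive_seed(spec$seed, .stage["graph"], s))
    if (group[s] == "B" && length(spec$affected_nodes))
      g <- degrade_nodes(g, spec$affected_nodes, spec$degradation_fraction,
                         seed = derive_seed(spec$seed, .stage["graph"], s, 99L))
    true_graphs[[s]] <- g
    timeseries[[s]] <- simulate_timeseries(
      g, spec$n_timepoints, edge_weight = spec$edge_weight,
      noise_sd = spec$noise_sd, tr = spec$tr_seconds,
      seed = derive_seed(spec$seed, .stage["timeseries"], s), id = ids[s])
    motion[[s]] <- local_seed(derive_seed(spec$seed, .stage["motion"], s), {
      spikes <- integer(0)
      if (stats::runif(1) < spec$spike_prob) {
        n_spk <- sample.int(spec$max_spikes, 1)
        spikes <- sort(sample(2:spec$n_timepoints, n_spk))
      }
      simulate_motion(spec$n_timepoints, spikes, spec$spike_amplitude)
    })
    enodal_behavior[s] <- nodal_efficiency(g)[spec$behavior_node]
  }

  ages <- local_seed(derive_seed(spec$seed, .stage["age"]),
                     round(stats::runif(n_sub, 14, 18), 1))

  sd_x <- stats::sd(enodal_behavior)
  noise_sd <- if (sd_x > 0)
    behavior_noise_for_r(spec$behavior_slope, sd_x, spec$behavior_r)
  else 1
  behavior <- data.frame(id = ids)
  scales <- c(total = 60, attention = 18, motor = 22, nonplanning = 27)
  for (nm in names(scales)) {
    behavior[[nm]] <- simulate_behavior(
      enodal_behavior, spec$behavior_slope, noise_sd,
      intercept = scales[[nm]],
      seed = derive_seed(spec$seed, .stage["behavior"], match(nm, names(scales))))
  }

  names(true_graphs) <- names(timeseries) <- names(motion) <- ids
  structure(
    list(subjects = data.frame(id = ids, group = group, age = ages,
                               stringsAsFactors = FALSE),
         timeseries = timeseries, motion = motion,
         true_graphs = true_graphs, behavior = behavior,
         true_nodal_values = enodal_behavior, spec = spec),
    class = "connectome_dataset"
  )
}

#' @export
print.connectome_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic connectome dataset: %d subjects (%s), %d nodes, %d frames\n",
    nrow(x$subjects),
    paste(sprintf("%s: %d", names(table(x$subjects$group)),
                  table(x$subjects$group)), collapse = ", "),
    x$spec$n_nodes, x$spec$n_timepoints))
  invisible(x)
}
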