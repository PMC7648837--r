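# Superparamagnetic clustering (SPC): a q-state Potts model on the
# K-nearest-neighbour graph of the spike features, simulated with
# Swendsen-Wang cluster dynamics across a temperature grid.  In the
# superparamagnetic phase only points that belong together change state
# simultaneously, so thresholding the point-point correlation at 0.5 and
# taking connected components recovers the clusters.

#' SPC tuning parameters
#'
#' @param K Nearest-neighbour count for the interaction graph (default 11).
#' @param n_iter Monte Carlo sweeps per temperature (default 500).
#' @param t_min,t_max,t_step Temperature grid (default 0 to 0.25 by 0.01).
#' @param min_cluster_size Smallest cluster treated as real; the effective
#'   value is `max(min_cluster_size, ceil(0.02 * n_spikes))`.
#' @param q Number of Potts states (default 20).
#' @param corr_threshold Point-point correlation threshold (default 0.5).
#' @param burn_frac Fraction of sweeps discarded as burn-in (default 0.1).
#' @return list of class `spc_params`.
#' @export
spc_params <- function(K = 11, n_iter = 500, t_min = 0, t_max = 0.25,
                       t_step = 0.01, min_cluster_size = 20, q = 20,
                       corr_threshold = 0.5, burn_frac = 0.1) {
  stopifnot(K >= 1, n_iter >= 1, t_step > 0, t_max >= t_min, t_min >= 0,
            q >= 2, corr_threshold > 0, corr_threshold < 1)
  structure(list(K = as.integer(K), n_iter = as.integer(n_iter),
                 t_min = t_min, t_max = t_max, t_step = t_step,
                 min_cluster_size = as.integer(min_cluster_size),
                 q = as.integer(q), corr_threshold = corr_threshold,
                 burn_frac = burn_frac),
            class = "spc_params")
}

# connected components of an undirected edge list; returns labels 1..C
# ordered by decreasing component size (ties by lowest member index)
edge_components <- function(n, ei, ej) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(ei)) {
    a <- find(ei[k]); b <- find(ej[k])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- table(roots)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relab <- integer(n)
  relab[as.integer(names(sizes))[ord]] <- seq_along(ord)
  relab[roots]
}

#' Cluster spike features with superparamagnetic clustering
#'
#' Builds the (symmetrised) K-nearest-neighbour graph, computes the
#' pairwise interaction `J_ij = (1/K) exp(-||x_i - x_j||^2 / (2 a^2))` with
#' `a` the average nearest-neighbours distance, and runs Swendsen-Wang
#' dynamics (bond probability `1 - exp(-J_ij / T)` between same-state
#' neighbours) at each temperature of the grid.  Neighbour pairs whose
#' point-point correlation exceeds the threshold are placed in the same
#' cluster (connected components).
#'
#' @param features n x d numeric matrix of selected spike features.
#' @param params An [spc_params()] object.
#' @param seed Integer seed for the Monte Carlo stream.
#' @return Object of class `spc_sweep`: list with `temperatures`, `labels`
#'   (n x n_temperatures integer matrix, component ids ordered by size),
#'   `edge_corr`, `edges`, `J`, `a`, `params`.
#' @export
spc_cluster <- function(features, params = spc_params(), seed = 1) {
  if (is.null(dim(features))) features <- matrix(features, ncol = 1)
  n <- nrow(features)
  if (n < 2) stop("need at least 2 spikes to cluster")
  K <- params$K
  if (K > n - 1) {
    warning("K reduced from ", K, " to ", n - 1)
    K <- n - 1L
  }
  d <- as.matrix(dist(features))
  # K nearest neighbours of every point; self is excluded explicitly
  # (duplicate points tie with self at distance 0)
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(K)]))
  diag(d) <- 0
  a <- mean(d[cbind(rep(seq_len(n), each = K), as.integer(t(nn)))])
  ei <- rep(seq_len(n), each = K)
  ej <- as.integer(t(nn))
  swap <- ei > ej
  tmp <- ei[swap]; ei[swap] <- ej[swap]; ej[swap] <- tmp
  keep <- !duplicated(cbind(ei, ej))
  ei <- ei[keep]; ej <- ej[keep]
  J <- (1 / K) * exp(-d[cbind(ei, ej)]^2 / (2 * a^2))
  temps <- seq(params$t_min, params$t_max, by = params$t_step)
  n_burn <- as.integer(ceiling(params$burn_frac * params$n_iter))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  corr <- spc_sweep_cpp(ei - 1L, ej - 1L, J, temps, n, params$n_iter,
                        params$q, n_burn)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  labels <- matrix(0L, n, length(temps))
  for (t in seq_along(temps)) {
    link <- corr[, t] > params$corr_threshold
    labels[, t] <- edge_components(n, ei[link], ej[link])
  }
  structure(list(temperatures = temps, labels = labels, edge_corr = corr,
                 edges = cbind(i = ei, j = ej), J = J, a = a,
                 params = params),
            class = "spc_sweep")
}

#' Pick the working temperature and final cluster labels
#'
#' Scans the temperature grid from cold to hot and selects the highest
#' temperature at which a new non-trivial cluster (size >=
#' `min_cluster_size`) appears relative to the previous temperature -- the
#' last structural split before clusters start dissolving, i.e. the
#' superparamagnetic phase.  (Near the dissolution temperature clusters
#' shed members, so the hottest temperature with any surviving cluster
#' systematically returns fragments; the last-split rule returns the
#' partition while it is still intact.)  At the chosen temperature points
#' inside non-trivial clusters get contiguous ids 1..C (largest first) and
#' all remaining points are labelled 0 (unassigned).  If no temperature
#' yields a non-trivial cluster, every spike is assigned to a single
#' cluster (single-unit fallback) with a warning.
#'
#' @param sweep An `spc_sweep` from [spc_cluster()].
#' @param min_cluster_size Minimum size of a real cluster; defaults to the
#'   value in the sweep's parameters.
#' @return list(chosen_temperature, final_labels).
#' @export
choose_temperature <- function(sweep, min_cluster_size = NULL) {
  stopifnot(inherits(sweep, "spc_sweep"))
  n <- nrow(sweep$labels)
  if (is.null(min_cluster_size))
    min_cluster_size <- max(sweep$params$min_cluster_size,
                            ceiling(0.02 * n))
  counts <- vapply(seq_along(sweep$temperatures), function(t)
    sum(table(sweep$labels[, t]) >= min_cluster_size), integer(1))
  run_max <- cummax(c(0L, counts))[seq_along(counts)]
  increases <- which(counts > run_max)   # count exceeds every colder count
  best <- if (length(increases)) max(increases) else NA_integer_
  if (is.na(best)) {
    warning("no cluster reaches the minimum size; single-unit fallback")
    return(list(chosen_temperature = sweep$temperatures[1],
                final_labels = rep(1L, n)))
  }
  lab <- sweep$labels[, best]
  sizes <- table(lab)
  real <- as.integer(names(sizes)[sizes >= min_cluster_size])
  # survivors keep their size order; everything else is unassigned
  relab <- integer(max(lab))
  relab[sort(real)] <- rank(-sizes[as.character(sort(real))],
                            ties.method = "first")
  final <- integer(n)
  inreal <- lab %in% real
  final[inreal] <- relab[lab[inreal]]
  list(chosen_temperature = sweep$temperatures[best], final_labels = final)
}

#' Full spike-sorting of one band-passed trace
#'
#' Detection, waveform extraction, Haar features, Lilliefors coefficient
#' selection and SPC clustering in one call.
#'
#' @param filtered Band-passed trace (see [bandpass_spike_filter()]).
#' @param fs Sampling rate in Hz.
#' @param k_thresh Detection threshold multiplier.
#' @param n_select Number of wavelet coefficients kept.
#' @param params An [spc_params()] object.
#' @param seed Monte Carlo seed.
#' @return Object of class `spike_sort_result`: `timestamps`, `waveforms`,
#'   `features`, `selected_coeff_idx`, `labels_by_temperature`,
#'   `temperatures`, `final_labels` (0 = unassigned), `chosen_temperature`.
#'   Degenerate sites (fewer than 2 usable spikes) come back with all
#'   spikes in cluster 1 and no temperature sweep.
#' @export
sort_spikes <- function(filtered, fs, k_thresh = 4, n_select = 10,
                        params = spc_params(), seed = 1) {
  ts <- detect_spikes(filtered, fs, k_thresh = k_thresh)
  wf <- extract_waveforms(filtered, ts, fs)
  n <- nrow(wf$waveforms)
  res <- list(timestamps = wf$timestamps, waveforms = wf$waveforms,
              features = NULL, selected_coeff_idx = integer(0),
              labels_by_temperature = NULL, temperatures = numeric(0),
              final_labels = rep(1L, n), chosen_temperature = NA_real_)
  class(res) <- "spike_sort_result"
  if (n < 2) {
    res$final_labels <- rep(1L, n)
    return(res)
  }
  feats <- haar_features(wf$waveforms)
  res$features <- feats
  sel <- select_coefficients(feats, n_select = n_select)
  res$selected_coeff_idx <- sel
  if (!length(sel)) return(res)  # indistinguishable shapes: one cluster
  sweep <- spc_cluster(feats[, sel, drop = FALSE], params = params,
                       seed = seed)
  res$labels_by_temperature <- sweep$labels
  res$temperatures <- sweep$temperatures
  ct <- choose_temperature(sweep)
  res$final_labels <- ct$final_labels
  res$chosen_temperature <- ct$chosen_temperature
  res
}
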