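#' Erdos-Renyi G(n, m) random graph
#'
#' m distinct edges sampled uniformly without replacement from all
#' unordered node pairs; simple and undirected.  Serves as the topology
#' null with the same node and edge counts as an observed network.
#'
#' @param n number of nodes.
#' @param m number of edges, between 0 and n(n-1)/2.
#' @param seed integer seed.
#' @return A `cooccur_network` with nodes `v001`, `v002`, ... of kind
#'   `"random"`; isolated nodes are kept (they count toward density and
#'   average degree).
#' @export
er_random_graph <- function(n, m, seed) {
  max_m <- n * (n - 1) / 2
  if (m < 0 || m > max_m)
    stop(sprintf("`m` must lie in [0, %d] for n = %d", max_m, n))
  set.seed(seed)
  g <- igraph::sample_gnm(n, m)
  ids <- sprintf("v%03d", seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(feature_a = ids[el[, 1L]], feature_b = ids[el[, 2L]],
                      stringsAsFactors = FALSE)
  new_network(data.frame(id = ids, kind = "random",
                         stringsAsFactors = FALSE),
              edges)
}

#' Topology summary over an ensemble of G(n, m) random graphs
#'
#' Generates `n_replicates` random graphs with fixed node and edge counts,
#' computes the full topological summary of each (with one seeded Louvain
#' run per replicate) and reports per-metric means and standard deviations.
#' Replicate seeds are derived from the master seed by a counter, so the
#' summary is bit-reproducible.
#'
#' @inheritParams er_random_graph
#' @param n_replicates ensemble size (default 10000); at least 2.
#' @param seed master seed; replicate i uses `(seed + i) mod (2^31 - 1)`.
#' @param cc_type passed to [topology_summary()].
#' @return A list of class `null_ensemble_summary`: `n_nodes`, `n_edges`,
#'   `n_replicates`, `seed`, `mean` and `sd` (named numeric vectors over
#'   the metrics), and `replicates` (the per-replicate metric matrix).
#' @export
null_ensemble <- function(n, m, n_replicates = 10000, seed = 1,
                          cc_type = c("global", "local_mean")) {
  cc_type <- match.arg(cc_type)
  if (n_replicates < 2) stop("`n_replicates` must be at least 2")
  metrics <- c("modularity", "clustering_coefficient",
               "average_path_length", "diameter", "average_degree",
               "density")
  reps <- matrix(NA_real_, n_replicates, length(metrics),
                 dimnames = list(NULL, metrics))
  for (i in seq_len(n_replicates)) {
    s_i <- (seed + i) %% 2147483647
    g <- er_random_graph(n, m, seed = s_i)
    part <- if (m > 0) louvain_partition(g, seed = s_i) else NULL
    ts <- topology_summary(g, part, cc_type = cc_type)
    reps[i, ] <- unlist(ts[metrics])
  }
  structure(list(n_nodes = n, n_edges = m, n_replicates = n_replicates,
                 seed = seed, cc_type = cc_type,
                 mean = colMeans(reps),
                 sd = apply(reps, 2L, stats::sd),
                 replicates = reps),
            class = "null_ensemble_summary")
}

#' @export
print.null_ensemble_summary <- function(x, ...) {
  cat(sprintf("G(%d, %d) ensemble, %d replicates (seed %d):\n",
              x$n_nodes, x$n_edges, x$n_replicates, x$seed))
  for (mt in names(x$mean))
    cat(sprintf("  %-24s %.3f +/- %.3f\n", mt, x$mean[mt], x$sd[mt]))
  invisible(x)
}

#' Compare observed topology with its random-graph null
#'
#' Per metric: the observed value, null mean and standard deviation, the
#' ratio observed/mean (NA when the null mean is 0) and the z-score
#' (obs - mean)/sd, reported NA ("undefined") when the null sd is 0.
#' The comparison is flagged `modular` when both observed modularity and
#' clustering coefficient exceed their null means, and `small_world` when
#' the clustering-coefficient ratio is at least 2 while the
#' average-path-length ratio stays within 25 % of 1 — high clustering at
#' near-random path length.
#'
#' @param observed a [topology_summary()].
#' @param null a [null_ensemble_summary][null_ensemble] with matching node
#'   and edge counts.
#' @return A data frame of class `null_comparison` with columns `metric`,
#'   `observed`, `null_mean`, `null_sd`, `ratio`, `z`; attributes
#'   `modular` and `small_world` carry the flags.
#' @export
compare_to_null <- function(observed, null) {
  stopifnot(inherits(observed, "topology_summary"),
            inherits(null, "null_ensemble_summary"))
  if (observed$n_nodes != null$n_nodes || observed$n_edges != null$n_edges)
    stop("observed and null sizes differ")
  metrics <- names(null$mean)
  obs <- unlist(observed[metrics])
  mu <- null$mean[metrics]
  sdv <- null$sd[metrics]
  out <- data.frame(metric = metrics,
                    observed = unname(obs),
                    null_mean = unname(mu),
                    null_sd = unname(sdv),
                    ratio = unname(ifelse(mu != 0, obs / mu, NA_real_)),
                    z = unname(ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)),
                    row.names = NULL, stringsAsFactors = FALSE)
  cc_ratio <- out$ratio[out$metric == "clustering_coefficient"]
  apl_ratio <- out$ratio[out$metric == "average_path_length"]
  attr(out, "modular") <-
    isTRUE(obs["modularity"] > mu["modularity"]) &&
    isTRUE(obs["clustering_coefficient"] > mu["clustering_coefficient"])
  attr(out, "small_world") <-
    isTRUE(cc_ratio >= 2) && isTRUE(abs(apl_ratio - 1) <= 0.25)
  class(out) <- c("null_comparison", class(out))
  out
}
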