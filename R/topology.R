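#' Degree of a node
#' @param net a `cooccur_network`.
#' @param node node id.
#' @return Number of incident edges.
#' @export
node_degree <- function(net, node) {
  stopifnot(inherits(net, "cooccur_network"))
  if (!node %in% net$nodes$id) stop("unknown node: ", node)
  sum(net$edges$feature_a == node) + sum(net$edges$feature_b == node)
}

degree_vector <- function(net) {
  deg <- stats::setNames(integer(n_nodes(net)), net$nodes$id)
  if (n_edges(net)) {
    tab <- table(c(net$edges$feature_a, net$edges$feature_b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Newman-Girvan modularity of a node partition
#'
#' Q = sum over modules c of \[ e_c / m - (d_c / 2m)^2 \], where e_c is the
#' number of edges inside c, d_c the total degree of c's nodes and m the
#' edge count.  Computed directly from the edge list, independently of any
#' community-detection code.
#'
#' @param net a `cooccur_network` with at least one edge.
#' @param membership module assignment named by node id (or in node order).
#' @return Modularity Q.
#' @export
modularity_q <- function(net, membership) {
  m <- n_edges(net)
  if (m == 0L) stop("modularity is undefined for an edgeless network")
  if (is.null(names(membership))) {
    if (length(membership) != n_nodes(net))
      stop("`membership` must cover every node")
    names(membership) <- net$nodes$id
  }
  if (!all(net$nodes$id %in% names(membership)))
    stop("`membership` must cover every node")
  ma <- membership[net$edges$feature_a]
  mb <- membership[net$edges$feature_b]
  e_within <- sum(ma == mb) / m
  deg <- degree_vector(net)
  d_c <- tapply(deg, membership[names(deg)], sum)
  e_within - sum((d_c / (2 * m))^2)
}

#' Louvain module detection
#'
#' Greedy modularity optimization by multi-level aggregation.  The node
#' traversal order is randomized by `seed` (the graph's vertices are
#' permuted before clustering), so distinct seeds give independent
#' restarts of the order-dependent heuristic.
#'
#' @param net a `cooccur_network` with at least one edge.
#' @param seed integer seed controlling the traversal order; `NULL` leaves
#'   the node order as is.
#' @return A list of class `module_partition`: `assignment` (module id per
#'   node, named, in node order), `n_modules`, and `q`, the partition's
#'   modularity recomputed with [modularity_q()].
#' @export
louvain_partition <- function(net, seed = NULL) {
  stopifnot(inherits(net, "cooccur_network"))
  if (n_edges(net) == 0L) stop("Louvain requires at least one edge")
  g <- as_igraph(net)
  if (!is.null(seed)) {
    set.seed(seed)
    g <- igraph::permute(g, sample(igraph::vcount(g)))
  }
  cl <- igraph::cluster_louvain(g)
  memb <- igraph::membership(cl)
  assignment <- as.integer(memb[net$nodes$id])
  names(assignment) <- net$nodes$id
  structure(list(assignment = assignment,
                 n_modules = length(unique(assignment)),
                 q = modularity_q(net, assignment)),
            class = "module_partition")
}

#' Best-of-restarts Louvain partition
#'
#' Louvain is order-dependent; this runs `restarts` seeded traversals and
#' keeps the partition with the highest modularity.  All Q values are
#' attached as attribute `q_runs`.
#'
#' @inheritParams louvain_partition
#' @param restarts number of seeded runs (default 10).
#' @param seed master seed; run i uses `seed + i - 1`.
#' @return The best `module_partition`.
#' @export
louvain_best <- function(net, restarts = 10, seed = 1) {
  runs <- lapply(seq_len(restarts),
                 function(i) louvain_partition(net, seed = seed + i - 1))
  qs <- vapply(runs, `[[`, numeric(1), "q")
  best <- runs[[which.max(qs)]]
  attr(best, "q_runs") <- qs
  best
}

#' Topological property summary of a network
#'
#' The six headline metrics: modularity (of the supplied partition),
#' clustering coefficient, average path length over connected sample
#' pairs, diameter (longest finite shortest path, i.e. the maximum within
#' components), average degree 2m/n and density 2m/(n(n-1)).
#'
#' @param net a non-empty `cooccur_network`.
#' @param partition optional `module_partition`; without one, modularity
#'   is reported as `NA`.
#' @param cc_type clustering-coefficient convention: `"global"` (default)
#'   is the transitivity ratio 3 x triangles / connected triples;
#'   `"local_mean"` averages local clustering over nodes of degree >= 2.
#'   A graph with no node of degree >= 2 has clustering coefficient 0
#'   under either convention.
#' @return A list of class `topology_summary` with fields `n_nodes`,
#'   `n_edges`, `modularity`, `clustering_coefficient`,
#'   `average_path_length`, `diameter`, `average_degree`, `density`.
#' @export
topology_summary <- function(net, partition = NULL,
                             cc_type = c("global", "local_mean")) {
  cc_type <- match.arg(cc_type)
  stopifnot(inherits(net, "cooccur_network"))
  n <- n_nodes(net)
  m <- n_edges(net)
  if (n == 0L) stop("empty network")
  g <- as_igraph(net)
  cc <- if (cc_type == "global") {
    igraph::transitivity(g, type = "global")
  } else {
    mean(igraph::transitivity(g, type = "local"), na.rm = TRUE)
  }
  if (!is.finite(cc)) cc <- 0  # no connected triples / no degree-2 node
  apl <- if (m > 0) igraph::mean_distance(g, directed = FALSE, unconn = TRUE)
         else NA_real_
  diam <- if (m > 0) igraph::diameter(g, directed = FALSE, unconn = TRUE)
          else 0
  q <- if (is.null(partition)) NA_real_
       else modularity_q(net, partition$assignment)
  structure(list(n_nodes = n, n_edges = m,
                 modularity = q,
                 clustering_coefficient = cc,
                 average_path_length = apl,
                 diameter = diam,
                 average_degree = 2 * m / n,
                 density = if (n > 1) 2 * m / (n * (n - 1)) else 0,
                 cc_type = cc_type),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0("Topology (%d nodes, %d edges): Q = %s, CC = %.3f, ",
                     "APL = %.3f, diameter = %s, AD = %.3f, density = %.3f\n"),
              x$n_nodes, x$n_edges,
              ifelse(is.na(x$modularity), "NA", sprintf("%.3f", x$modularity)),
              x$clustering_coefficient, x$average_path_length,
              format(x$diameter), x$average_degree, x$density))
  invisible(x)
}

#' Observed and random co-occurrence incidence per module
#'
#' For each module c, the observed incidence is the percentage of the
#' network's edges with both endpoints in c; the random incidence is the
#' percentage expected under random association given the module sizes,
#' 100 * n_c (n_c - 1) / (n (n - 1)).  Modules whose observed incidence
#' exceeds the random expectation are flagged as non-random co-occurrence.
#'
#' @param net a `cooccur_network` with at least one edge.
#' @param partition a `module_partition` covering the network.
#' @return A data frame with columns `module`, `n_nodes`,
#'   `observed_incidence`, `random_incidence` (both percent) and
#'   `non_random`.
#' @export
module_incidence <- function(net, partition) {
  stopifnot(inherits(net, "cooccur_network"),
            inherits(partition, "module_partition"))
  m <- n_edges(net)
  if (m == 0L) stop("incidence is undefined for an edgeless network")
  n <- n_nodes(net)
  memb <- partition$assignment
  if (!all(net$nodes$id %in% names(memb)))
    stop("partition does not cover the network")
  mods <- sort(unique(memb[net$nodes$id]))
  ma <- memb[net$edges$feature_a]
  mb <- memb[net$edges$feature_b]
  out <- do.call(rbind, lapply(mods, function(cmod) {
    n_c <- sum(memb[net$nodes$id] == cmod)
    within <- sum(ma == cmod & mb == cmod)
    data.frame(module = cmod, n_nodes = n_c,
               observed_incidence = 100 * within / m,
               random_incidence = 100 * n_c * (n_c - 1) / (n * (n - 1)))
  }))
  out$non_random <- out$observed_incidence > out$random_incidence
  rownames(out) <- NULL
  out
}

#' Highest-degree nodes of a network
#'
#' Candidate hubs ("connection centers"): nodes ranked by degree
#' descending, ties broken lexicographically by node id.
#'
#' @param net a non-empty `cooccur_network`.
#' @param top_k how many nodes to return.
#' @return A data frame with columns `id`, `kind`, `degree`.
#' @export
hub_nodes <- function(net, top_k) {
  stopifnot(inherits(net, "cooccur_network"))
  if (top_k < 1) stop("`top_k` must be at least 1")
  deg <- degree_vector(net)
  ord <- order(-deg, names(deg))
  sel <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(id = names(deg)[sel],
             kind = net$nodes$kind[match(names(deg)[sel], net$nodes$id)],
             degree = as.integer(deg[sel]),
             row.names = NULL, stringsAsFactors = FALSE)
}
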