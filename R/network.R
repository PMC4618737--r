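## All permutations of 1..n as rows (n! x n); used by the exact Spearman
## permutation null.  Intended for small n only.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)), deparse.level = 0)
  }))
}

#' All-pairs Spearman correlations of a feature table
#'
#' Computes Spearman's rank correlation (average ranks for ties) for every
#' unordered feature pair of the table — gene-family/gene-family,
#' taxon/taxon and gene-family/taxon pairs alike — together with a
#' two-sided p-value.  Constant (zero-variance) features cannot be ranked
#' informatively; their pairs are skipped with a warning.
#'
#' @param table an [abundance_table()], typically the [combine_features()]
#'   stack of the filtered gene-family and taxon tables.
#' @param p_method `"t_approx"` (default): p from the t transform
#'   t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom.
#'   `"exact_permutation"`: enumerate all n! orderings of one variable
#'   (feasible for n <= 9 samples; larger n falls back to `t_approx` with
#'   a warning).
#' @param seed unused by either method (both are deterministic); kept so
#'   callers can treat every pipeline stage uniformly.
#' @return A data frame of pre-threshold edges: `feature_a`, `feature_b`,
#'   `kind_a`, `kind_b`, `rho`, `rho_squared`, `p_raw`, `sign`
#'   (`"positive"` iff rho > 0).
#' @export
spearman_all_pairs <- function(table,
                               p_method = c("t_approx", "exact_permutation"),
                               seed = NULL) {
  p_method <- match.arg(p_method)
  stopifnot(inherits(table, "abund_table"))
  v <- table$values
  n <- ncol(v)
  if (n < 4L) stop("at least 4 samples are required")
  const <- apply(v, 1L, function(z) diff(range(z)) == 0)
  if (any(const))
    warning("skipping constant feature(s): ",
            paste(rownames(v)[const], collapse = ", "))
  v <- v[!const, , drop = FALSE]
  kinds <- table$feature_kinds[!const]
  if (nrow(v) < 2L) stop("fewer than 2 non-constant features")
  rk <- t(apply(v, 1L, rank))
  rho_m <- stats::cor(t(rk))
  ut <- which(upper.tri(rho_m), arr.ind = TRUE)
  rho <- rho_m[ut]
  if (p_method == "exact_permutation" && n > 9L) {
    warning("exact permutation null is limited to 9 samples; ",
            "falling back to the t approximation")
    p_method <- "t_approx"
  }
  if (p_method == "t_approx") {
    denom <- 1 - rho^2
    p <- ifelse(denom <= .Machine$double.eps,
                0,
                2 * stats::pt(abs(rho) * sqrt((n - 2) / pmax(denom, 1e-300)),
                              df = n - 2, lower.tail = FALSE))
    p <- pmin(p, 1)
  } else {
    perms <- all_permutations(n)
    p <- vapply(seq_len(nrow(ut)), function(e) {
      ra <- rk[ut[e, 1L], ] - mean(rk[ut[e, 1L], ])
      rb <- rk[ut[e, 2L], ] - mean(rk[ut[e, 2L], ])
      denom <- sqrt(sum(ra^2) * sum(rb^2))
      rho_perm <- (matrix(rb[perms], nrow(perms)) %*% ra) / denom
      mean(abs(rho_perm) >= abs(rho[e]) - 1e-12)
    }, numeric(1))
  }
  data.frame(feature_a = rownames(v)[ut[, 1L]],
             feature_b = rownames(v)[ut[, 2L]],
             kind_a = kinds[ut[, 1L]],
             kind_b = kinds[ut[, 2L]],
             rho = rho,
             rho_squared = rho^2,
             p_raw = p,
             sign = ifelse(rho > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment of correlation p-values
#'
#' Applied jointly over all tested pairs.  Benjamini-Hochberg is the
#' step-up FDR adjustment p_adj(i) = min over j >= i of p(j) * m / j,
#' monotone-enforced and capped at 1.
#'
#' @param p_raw vector of raw p-values in \[0, 1\].
#' @param method `"benjamini_hochberg"` (default) or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p_raw,
                           method = c("benjamini_hochberg", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p_raw)) || any(p_raw < 0 | p_raw > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_raw, method = switch(method,
                                         benjamini_hochberg = "BH",
                                         bonferroni = "bonferroni"))
}

#' Robust-edge retention criteria
#'
#' An edge is "robust" when the correlation is strong — by default the
#' SQUARED Spearman coefficient exceeds `rho_squared_min` (the literal
#' r^2 > 0.6 reading, i.e. |rho| > 0.775) — and its adjusted p-value falls
#' below `p_adj_max`.  `threshold_on = "abs_rho"` switches the strength
#' test to |rho| > `rho_squared_min` for the alternative reading.
#'
#' @param rho_squared_min strength threshold (default 0.6).
#' @param p_adj_max adjusted-p threshold (default 0.05).
#' @param correction_method multiple-testing method, see [adjust_pvalues()].
#' @param threshold_on `"rho2"` (default) or `"abs_rho"`.
#' @return A list of class `edge_criteria`.
#' @export
edge_criteria <- function(rho_squared_min = 0.6, p_adj_max = 0.05,
                          correction_method = c("benjamini_hochberg",
                                                "bonferroni"),
                          threshold_on = c("rho2", "abs_rho")) {
  correction_method <- match.arg(correction_method)
  threshold_on <- match.arg(threshold_on)
  if (rho_squared_min <= 0 || rho_squared_min > 1)
    stop("`rho_squared_min` must lie in (0, 1]")
  if (p_adj_max <= 0 || p_adj_max > 1)
    stop("`p_adj_max` must lie in (0, 1]")
  structure(list(rho_squared_min = rho_squared_min, p_adj_max = p_adj_max,
                 correction_method = correction_method,
                 threshold_on = threshold_on),
            class = "edge_criteria")
}

#' Construct a network from node and edge tables
#'
#' Low-level constructor used by [build_network()], [er_random_graph()]
#' and tests; validates that the graph is simple (no self-loops or
#' duplicate edges) and that every edge endpoint is a node.
#'
#' @param nodes data frame with columns `id` and `kind`.
#' @param edges data frame with columns `feature_a` and `feature_b` (plus
#'   any edge statistics).
#' @return A `cooccur_network`.
#' @export
new_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), all(c("id", "kind") %in% names(nodes)),
            is.data.frame(edges),
            all(c("feature_a", "feature_b") %in% names(edges)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (nrow(edges)) {
    if (any(edges$feature_a == edges$feature_b))
      stop("self-loops are not allowed")
    key <- paste(pmin(edges$feature_a, edges$feature_b),
                 pmax(edges$feature_a, edges$feature_b))
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    if (!all(c(edges$feature_a, edges$feature_b) %in% nodes$id))
      stop("edge endpoints must be nodes of the network")
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cooccur_network")
}

#' Number of nodes / edges of a network
#' @param net a `cooccur_network`.
#' @return An integer count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' @export
print.cooccur_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d nodes, %d edges\n",
              n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Build the co-occurrence network from pre-threshold correlations
#'
#' Adjusts the raw p-values jointly over all tested pairs, then retains an
#' edge iff its strength exceeds the threshold AND its adjusted p-value
#' falls below `p_adj_max`.  The node set is the set of features incident
#' to at least one retained edge.
#'
#' @param edges pre-threshold edge data frame from [spearman_all_pairs()].
#' @param criteria an [edge_criteria()].
#' @return A `cooccur_network` whose `edges` carry `p_adj`.
#' @export
build_network <- function(edges, criteria = edge_criteria()) {
  stopifnot(inherits(criteria, "edge_criteria"))
  edges$p_adj <- adjust_pvalues(edges$p_raw, criteria$correction_method)
  strength <- switch(criteria$threshold_on,
                     rho2 = edges$rho_squared,
                     abs_rho = abs(edges$rho))
  keep <- strength > criteria$rho_squared_min & edges$p_adj < criteria$p_adj_max
  kept <- edges[keep, , drop = FALSE]
  nodes <- unique(data.frame(
    id = c(kept$feature_a, kept$feature_b),
    kind = c(kept$kind_a, kept$kind_b),
    stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  new_network(nodes, kept)
}

#' Split a network into its positive and negative sub-networks
#'
#' Edges are partitioned by correlation sign; each sub-network's node set
#' is recomputed from its own edges, so a node incident to both signs
#' appears in both sub-networks and node counts need not sum to the
#' whole network's.
#'
#' @param net a `cooccur_network` whose edges carry a `sign` column.
#' @return A list with elements `positive` and `negative`.
#' @export
split_by_sign <- function(net) {
  stopifnot(inherits(net, "cooccur_network"))
  if (n_edges(net) && !"sign" %in% names(net$edges))
    stop("edges carry no `sign`; not a correlation network")
  sub <- function(s) {
    e <- net$edges[n_edges(net) > 0 & net$edges$sign == s, , drop = FALSE]
    ids <- unique(c(e$feature_a, e$feature_b))
    nodes <- net$nodes[net$nodes$id %in% ids, , drop = FALSE]
    new_network(nodes, e)
  }
  list(positive = sub("positive"), negative = sub("negative"))
}

#' Convert a network to an igraph object
#'
#' Node `kind` and all edge statistics are carried as attributes.
#'
#' @param net a `cooccur_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooccur_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write the network edge list as TSV
#' @param net a `cooccur_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the network as GraphML
#'
#' Nodes carry their `kind`, edges their correlation statistics, so the
#' file can be styled directly in Gephi or Cytoscape.
#'
#' @param net a `cooccur_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
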