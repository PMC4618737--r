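# Shared fixture builders.  Everything is generated in code; no data files.

toy_table <- function(values, kinds = "gene_family", unit = "fraction") {
  abundance_table(values, feature_kinds = kinds, unit = unit)
}

# A small features-x-samples matrix with named dims.
toy_matrix <- function(values, features, samples) {
  matrix(values, nrow = length(features),
         dimnames = list(features, samples))
}

# Build a network from an edge list given as a 2-column matrix / data frame
# of endpoint ids; extra columns (rho, sign, ...) are carried through.
fixture_network <- function(edges, nodes = NULL, kinds = "gene_family") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("feature_a", "feature_b")
  ids <- if (is.null(nodes)) sort(unique(c(edges$feature_a, edges$feature_b)))
         else nodes
  new_network(data.frame(id = ids, kind = rep_len(kinds, length(ids)),
                         stringsAsFactors = FALSE),
              edges)
}

triangle_net <- function(ids = c("a", "b", "c")) {
  fixture_network(data.frame(feature_a = ids[c(1, 1, 2)],
                             feature_b = ids[c(2, 3, 3)]))
}

path4_net <- function() {
  fixture_network(data.frame(feature_a = c("a", "b", "c"),
                             feature_b = c("b", "c", "d")))
}

star_net <- function(n_leaves = 5) {
  fixture_network(data.frame(feature_a = "hub",
                             feature_b = sprintf("leaf%d", seq_len(n_leaves))))
}

two_triangles_net <- function() {
  fixture_network(data.frame(
    feature_a = c("a", "a", "b", "x", "x", "y"),
    feature_b = c("b", "c", "c", "y", "z", "z")))
}

complete_net <- function(n) {
  ids <- letters[seq_len(n)]
  pr <- t(utils::combn(ids, 2))
  fixture_network(data.frame(feature_a = pr[, 1], feature_b = pr[, 2]))
}

# Graphs exercised by the Louvain-vs-recomputed-modularity oracle check.
oracle_graphs <- function() {
  list(triangle = triangle_net(), path4 = path4_net(), star = star_net(),
       two_triangles = two_triangles_net(), k5 = complete_net(5),
       er = er_random_graph(20, 30, seed = 7))
}

# Euclidean distance matrix from a coordinate matrix.
euclid_dm <- function(coords) {
  d <- as.matrix(stats::dist(coords))
  rownames(d) <- colnames(d) <- rownames(coords)
  d
}
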