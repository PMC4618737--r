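spear_table <- function(rows, samples = sprintf("s%d", seq_len(ncol(rows)))) {
  colnames(rows) <- samples
  # scale rows into valid fractions without changing ranks
  m <- rows / (max(rows) * nrow(rows) * 2)
  toy_table(m)
}

test_that("Spearman rho matches hand-ranked values and the tie-free formula", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 3, 2, 5, 4)
  tab <- spear_table(rbind(fx = x, fy = y))
  e <- spearman_all_pairs(tab)
  # ranks of y are (1, 3, 2, 5, 4): sum d^2 = 4, n = 5, so the tie-free
  # formula gives rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(e$rho, 1 - 6 * sum((rank(x) - rank(y))^2) / (5 * 24))
  expect_equal(e$rho, 0.8)
  expect_equal(e$rho_squared, 0.64)

  mono <- spearman_all_pairs(spear_table(rbind(a = x, b = x^3)))
  expect_equal(mono$rho, 1)
  rev <- spearman_all_pairs(spear_table(rbind(a = x, b = rev(x))))
  expect_equal(rev$rho, -1)
  expect_identical(rev$sign, "negative")
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(41)
  x <- stats::rexp(8)
  y <- stats::rexp(8)
  base <- spearman_all_pairs(spear_table(rbind(a = x, b = y)))
  warped <- spearman_all_pairs(spear_table(rbind(a = exp(2 * x),
                                                 b = sqrt(y))))
  expect_equal(warped$rho, base$rho)
  expect_equal(warped$p_raw, base$p_raw)
})

test_that("t-approximation p agrees with cor.test and exact enumeration with the exact null", {
  set.seed(43)
  x <- stats::rexp(7)
  y <- 0.6 * x + stats::rexp(7)
  tab <- spear_table(rbind(a = x, b = y))
  approx <- spearman_all_pairs(tab, p_method = "t_approx")
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  expect_equal(approx$rho, unname(ref$estimate))
  expect_equal(approx$p_raw, ref$p.value, tolerance = 1e-10)

  exact <- spearman_all_pairs(tab, p_method = "exact_permutation")
  ref_ex <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(exact$rho, approx$rho)
  expect_equal(exact$p_raw, ref_ex$p.value, tolerance = 1e-12)
})

test_that("constant features are skipped with a warning, not an error", {
  m <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 5),
             flat = rep(1, 5))
  expect_warning(e <- spearman_all_pairs(spear_table(m)), "flat")
  expect_equal(nrow(e), 1L)
  expect_setequal(c(e$feature_a, e$feature_b), c("a", "b"))
})

test_that("BH adjustment reproduces the hand step-up and p.adjust", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # step-up by hand: min over j >= i of p(j) * m / j = 0.04 for every i
  expect_equal(adjust_pvalues(p), rep(0.04, 4))
  expect_equal(adjust_pvalues(0.42), 0.42)
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  set.seed(44)
  pr <- stats::runif(20)
  expect_equal(adjust_pvalues(pr), stats::p.adjust(pr, "BH"))
  expect_equal(adjust_pvalues(pr, "bonferroni"),
               stats::p.adjust(pr, "bonferroni"))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("edge retention applies the r^2 and adjusted-p rules jointly", {
  edges <- data.frame(
    feature_a = c("a", "c", "e"), feature_b = c("b", "d", "f"),
    kind_a = "gene_family", kind_b = "taxon",
    rho = c(0.9, 0.7, -0.9),
    rho_squared = c(0.81, 0.49, 0.81),
    p_raw = c(0.001, 0.0001, 0.02),
    sign = c("positive", "positive", "negative"),
    stringsAsFactors = FALSE)
  # BH over the three pairs: 0.003, 0.0003, 0.02
  net <- build_network(edges, edge_criteria())
  expect_equal(n_edges(net), 2L)           # rho^2 0.49 fails the strength rule
  expect_setequal(net$edges$feature_a, c("a", "e"))

  # the same rho = -0.9 edge fails once its adjusted p is too large
  edges$p_raw <- c(0.001, 0.0001, 0.2)
  net2 <- build_network(edges, edge_criteria())
  expect_equal(n_edges(net2), 1L)

  # |rho| > 0.6 reading retains the rho = 0.7 pair
  net3 <- build_network(edges, edge_criteria(threshold_on = "abs_rho"))
  expect_true("c" %in% net3$nodes$id)
})

test_that("sign split partitions edges and recomputes node sets", {
  edges <- data.frame(
    feature_a = c("a", "b"), feature_b = c("b", "c"),
    kind_a = c("gene_family", "taxon"), kind_b = c("taxon", "gene_family"),
    rho = c(0.95, -0.95), rho_squared = 0.9025,
    p_raw = c(0.001, 0.001), sign = c("positive", "negative"),
    stringsAsFactors = FALSE)
  net <- build_network(edges, edge_criteria())
  subs <- split_by_sign(net)
  expect_equal(n_edges(subs$positive) + n_edges(subs$negative), n_edges(net))
  expect_setequal(subs$positive$nodes$id, c("a", "b"))
  expect_setequal(subs$negative$nodes$id, c("b", "c"))  # b carries both signs
  expect_true(all(subs$positive$nodes$id %in% net$nodes$id))
  all_pos <- build_network(edges[1, ], edge_criteria())
  empty_neg <- split_by_sign(all_pos)$negative
  expect_equal(n_nodes(empty_neg), 0L)
  expect_equal(n_edges(empty_neg), 0L)
})

test_that("network construction is deterministic and simple", {
  fx <- fixture_paper_shape(seed = 6)
  edges <- spearman_all_pairs(fx$table)
  n1 <- build_network(edges, edge_criteria())
  n2 <- build_network(edges, edge_criteria())
  expect_identical(n1, n2)
  expect_false(any(n1$edges$feature_a == n1$edges$feature_b))
  # stricter significance can only shrink the edge set
  n_strict <- build_network(edges, edge_criteria(p_adj_max = 0.01))
  expect_lte(n_edges(n_strict), n_edges(n1))
})

test_that("edge-list and GraphML writers emit readable files", {
  net <- build_network(data.frame(
    feature_a = "a", feature_b = "b", kind_a = "gene_family",
    kind_b = "taxon", rho = 0.95, rho_squared = 0.9025, p_raw = 0.001,
    sign = "positive", stringsAsFactors = FALSE), edge_criteria())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_edge_list(net, tsv)
  expect_equal(nrow(utils::read.delim(tsv)), 1L)
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 2)
  expect_setequal(igraph::vertex_attr(g, "kind"), c("gene_family", "taxon"))
})
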