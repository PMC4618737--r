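test_that("degrees and hub ranking follow the degree/tie-break contract", {
  tri <- triangle_net()
  expect_equal(node_degree(tri, "a"), 2)
  expect_error(node_degree(tri, "zz"), "unknown node")
  st <- star_net(5)
  expect_equal(node_degree(st, "hub"), 5)
  expect_identical(hub_nodes(st, 1)$id, "hub")
  expect_error(hub_nodes(st, 0), "at least 1")

  # planted hub with degrees (4, 2, 2, ...) comes first; ties lexicographic
  net <- fixture_network(data.frame(
    feature_a = c("hub", "hub", "hub", "hub", "beta", "alpha"),
    feature_b = c("alpha", "beta", "gamma", "delta", "gamma", "delta")))
  hb <- hub_nodes(net, 3)
  expect_identical(hb$id, c("hub", "alpha", "beta"))
  expect_equal(hb$degree, c(4L, 2L, 2L))
})

test_that("topology summary matches exhaustively hand-computed small graphs", {
  tri <- topology_summary(triangle_net())
  expect_equal(tri$clustering_coefficient, 1)
  expect_equal(tri$average_path_length, 1)
  expect_equal(tri$diameter, 1)
  expect_equal(tri$average_degree, 2)
  expect_equal(tri$density, 1)

  # path a-b-c-d: pair distances 1,1,1,2,2,3
  p4 <- topology_summary(path4_net())
  expect_equal(p4$average_degree, 1.5)
  expect_equal(p4$density, 0.5)
  expect_equal(p4$average_path_length, (3 * 1 + 2 * 2 + 1 * 3) / 6)
  expect_equal(p4$diameter, 3)
  expect_equal(p4$clustering_coefficient, 0)
  expect_error(topology_summary(new_network(
    data.frame(id = character(), kind = character()),
    data.frame(feature_a = character(), feature_b = character()))),
    "empty")
})

test_that("average degree and density identities hold on random graphs", {
  for (seed in 1:5) {
    g <- er_random_graph(25, 40 + seed, seed = seed)
    ts <- topology_summary(g)
    expect_equal(ts$average_degree, 2 * n_edges(g) / n_nodes(g))
    expect_equal(ts$density, ts$average_degree / (n_nodes(g) - 1))
    expect_gte(ts$diameter, ts$average_path_length)
  }
})

test_that("clustering conventions agree on triangle-free and clique graphs", {
  neg_like <- path4_net()  # triangle-free
  expect_equal(topology_summary(neg_like, cc_type = "global")$clustering_coefficient, 0)
  expect_equal(topology_summary(neg_like, cc_type = "local_mean")$clustering_coefficient, 0)
  k5 <- complete_net(5)
  expect_equal(topology_summary(k5, cc_type = "global")$clustering_coefficient, 1)
  expect_equal(topology_summary(k5, cc_type = "local_mean")$clustering_coefficient, 1)
  # no node of degree >= 2: reported as 0 under either convention
  pair <- fixture_network(data.frame(feature_a = "a", feature_b = "b"))
  expect_equal(topology_summary(pair, cc_type = "global")$clustering_coefficient, 0)
  expect_equal(topology_summary(pair, cc_type = "local_mean")$clustering_coefficient, 0)
})

test_that("Louvain recovers provable partitions with the right modularity", {
  tt <- two_triangles_net()
  part <- louvain_partition(tt, seed = 1)
  expect_equal(part$n_modules, 2)
  expect_equal(part$q, 0.5)  # 2 * (3/6 - (6/12)^2)
  expect_equal(length(unique(part$assignment[c("a", "b", "c")])), 1)
  expect_equal(length(unique(part$assignment[c("x", "y", "z")])), 1)

  k5 <- complete_net(5)
  pk <- louvain_partition(k5, seed = 1)
  expect_equal(pk$n_modules, 1)
  expect_equal(pk$q, 0)

  # planted two dense blocks joined by a single cross edge
  blk <- function(ids) t(utils::combn(ids, 2))
  e <- rbind(blk(sprintf("p%d", 1:5)), blk(sprintf("q%d", 1:5)),
             c("p1", "q1"))
  net <- fixture_network(data.frame(feature_a = e[, 1], feature_b = e[, 2]))
  pp <- louvain_partition(net, seed = 3)
  expect_equal(pp$n_modules, 2)
  expect_equal(length(unique(pp$assignment[sprintf("p%d", 1:5)])), 1)
  expect_equal(length(unique(pp$assignment[sprintf("q%d", 1:5)])), 1)
  expect_error(louvain_partition(fixture_network(
    data.frame(feature_a = character(), feature_b = character()),
    nodes = "a")), "at least one edge")
})

test_that("Louvain's Q equals igraph's modularity of the same assignment", {
  for (net in oracle_graphs()) {
    part <- louvain_partition(net, seed = 11)
    g <- as_igraph(net)
    ref <- igraph::modularity(g, part$assignment[igraph::V(g)$name])
    expect_equal(part$q, ref, tolerance = 1e-12)
  }
})

test_that("best-of-restarts keeps the highest-Q run and logs all runs", {
  net <- er_random_graph(30, 45, seed = 2)
  best <- louvain_best(net, restarts = 8, seed = 5)
  qs <- attr(best, "q_runs")
  expect_length(qs, 8)
  expect_equal(best$q, max(qs))
})

test_that("module incidence matches direct counts and its bounds", {
  tt <- two_triangles_net()
  part <- louvain_partition(tt, seed = 1)
  inc <- module_incidence(tt, part)
  expect_equal(inc$observed_incidence, c(50, 50))
  expect_equal(inc$random_incidence, rep(100 * 3 * 2 / (6 * 5), 2))
  expect_true(all(inc$non_random))

  # single-module partition: everything observed and expected
  k4 <- complete_net(4)
  one <- louvain_partition(k4, seed = 1)
  inc1 <- module_incidence(k4, one)
  expect_equal(inc1$observed_incidence, 100)
  expect_equal(inc1$random_incidence, 100)

  # star K1,4 with {hub, leaf1} as a module: observed 25 %, random 10 %
  st <- star_net(4)
  manual <- structure(list(
    assignment = c(hub = 1L, leaf1 = 1L, leaf2 = 2L, leaf3 = 2L,
                   leaf4 = 2L),
    n_modules = 2L, q = NA_real_), class = "module_partition")
  inc2 <- module_incidence(st, manual)
  expect_equal(inc2$observed_incidence[inc2$module == 1], 25)
  expect_equal(inc2$random_incidence[inc2$module == 1],
               100 * 2 * 1 / (5 * 4))

  # observed incidences sum to 100 iff there is no inter-module edge
  expect_equal(sum(inc$observed_incidence), 100)
  expect_lte(sum(inc2$observed_incidence), 100)
})
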