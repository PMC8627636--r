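two_cliques <- function(s = 3, w = 1) {
  n <- 2 * s
  W <- matrix(0, n, n)
  W[1:s, 1:s] <- w
  W[(s + 1):n, (s + 1):n] <- w
  graph_from_weights(W)
}

test_that("modularity matches hand values and igraph", {
  g <- two_cliques()
  expect_equal(modularity_q(g, rep(1:2, each = 3)), 0.5)
  expect_equal(modularity_q(g, rep(1, 6)), 0)
  # edgeless graph guard
  g0 <- graph_from_weights(matrix(0, 3, 3))
  expect_equal(modularity_q(g0, 1:3), 0)
  # cross-check against igraph on random graphs and partitions
  set.seed(11)
  for (rep in 1:10) {
    g2 <- random_weighted_graph(7)
    part <- sample(1:3, 7, replace = TRUE)
    ig <- igraph::graph_from_adjacency_matrix(g2$weights, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(modularity_q(g2, part),
                 igraph::modularity(ig, part, weights = igraph::E(ig)$weight),
                 tolerance = 1e-12)
  }
  expect_error(modularity_q(g, c(1, 1, 1)), "every graph node")
})

test_that("modularity gain equals the brute-force modularity difference", {
  # two disjoint unit edges; inserting an endpoint of one into the other pair:
  # k_iin = 0, sigma_tot = 2, k_i = 1, m = 2 -> -0.25
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  g <- graph_from_weights(W)
  expect_equal(modularity_gain(g, c(1, 1, 2, 3), 3, 1), -0.25)

  # isolated node: zero gain anywhere
  W2 <- matrix(0, 3, 3); W2[1, 2] <- W2[2, 1] <- 1
  g2 <- graph_from_weights(W2)
  expect_equal(modularity_gain(g2, c(1, 1, 2), 3, 1), 0)

  # property: gain == Q(node in target) - Q(node singleton), random graphs
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    g3 <- random_weighted_graph(n)
    part <- sample(1:3, n, replace = TRUE)
    node <- sample(n, 1)
    targets <- setdiff(unique(part[-node]), integer(0))
    for (tg in targets) {
      with_node <- part; with_node[node] <- tg
      singleton <- part; singleton[node] <- max(part) + 1L
      expect_lt(abs(modularity_gain(g3, part, node, tg) -
                      (modularity_q(g3, with_node) -
                         modularity_q(g3, singleton))),
                1e-12)
    }
  }
})

test_that("louvain separates disconnected cliques and is reproducible", {
  g <- two_cliques()
  cl <- louvain(g, seed = 1)
  expect_equal(cl$k, 2)
  expect_equal(unname(cl$membership), rep(1:2, each = 3))
  expect_identical(louvain(g, seed = 9)$membership,
                   louvain(g, seed = 9)$membership)
  # modularity never decreases across aggregation levels
  expect_true(all(diff(cl$q_history) >= -1e-10))
  # output at least as good as the singleton partition
  expect_gte(cl$modularity, modularity_q(g, seq_along(g$gene_ids)))
})

test_that("louvain recovers planted correlated blocks", {
  aris <- vapply(1:5, function(s) {
    sim <- generate_dataset(seed = s)
    graph <- apply_edge_threshold(
      normalize_similarities(pearson_similarity_matrix(sim$dataset)), 0.6)
    cl <- louvain(graph, seed = s)
    in_block <- !is.na(sim$truth$block)
    adjusted_rand_index(cl$membership[in_block], sim$truth$block[in_block])
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("edgeless graphs degrade to singleton clusters with a warning", {
  g <- graph_from_weights(matrix(0, 4, 4))
  expect_warning(cl <- louvain(g, seed = 1), "singleton")
  expect_equal(cl$k, 4)
  expect_equal(cl$modularity, 0)
})

test_that("larger modularity runs agree with igraph louvain quality", {
  # not label-identical (visit order differs) but comparable partition quality
  set.seed(31)
  sim <- generate_dataset(seed = 31)
  graph <- apply_edge_threshold(
    normalize_similarities(pearson_similarity_matrix(sim$dataset)), 0.6)
  ours <- louvain(graph, seed = 31)
  ig <- igraph::graph_from_adjacency_matrix(graph$weights, mode = "undirected",
                                            weighted = TRUE)
  ref <- igraph::cluster_louvain(ig, weights = igraph::E(ig)$weight)
  q_ref <- igraph::modularity(ig, igraph::membership(ref),
                              weights = igraph::E(ig)$weight)
  expect_gte(ours$modularity, q_ref - 0.02)
})
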