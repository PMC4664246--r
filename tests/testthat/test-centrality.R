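# Dynamics-weighted shortest paths, path multiplicities, normalized
# betweenness, ensemble averaging, distributions, cluster means.

test_that("edge weights are -log|C| with floor and correlation filter", {
  g <- graph_from_pairs(c("a-b", "b-c", "a-c"))
  C <- matrix(c(1, 1, 0.5, 1, 1, 0, 0.5, 0, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  gw <- assign_edge_weights(g, C, c_min = NULL)
  w <- igraph::E(gw)$weight
  ends <- igraph::as_edgelist(gw)
  expect_equal(w[ends[, 1] == "a" & ends[, 2] == "b"], 0)           # |C|=1
  expect_equal(w[(ends[, 1] == "a" & ends[, 2] == "c") |
                 (ends[, 1] == "c" & ends[, 2] == "a")], log(2))    # |C|=0.5
  expect_equal(w[(ends[, 1] == "b" & ends[, 2] == "c") |
                 (ends[, 1] == "c" & ends[, 2] == "b")], -log(1e-8))  # floored
  # c_min filter removes weak edges before pathfinding
  gf <- assign_edge_weights(g, C, c_min = 0.5)
  expect_equal(igraph::ecount(gf), 2L)
  # signed filter drops anti-correlations that the |C| filter keeps
  Cn <- C; Cn["a", "c"] <- Cn["c", "a"] <- -0.8
  expect_equal(igraph::ecount(assign_edge_weights(g, Cn, c_min = 0.5)), 2L)
  expect_equal(igraph::ecount(assign_edge_weights(g, Cn, c_min = 0.5,
                                                  signed = TRUE)), 1L)
  expect_error(assign_edge_weights(graph_from_pairs("a-z"), C),
               class = "allonet_coverage_error")
})

test_that("path counting on hand-checked graphs", {
  # path 1-2-3 with unit weights
  g <- graph_from_pairs(c("1-2", "2-3"))
  pc <- shortest_path_counts(g)
  i <- match(c("1", "2", "3"), pc$nodes)
  expect_equal(pc$dist[i[1], i[3]], 2)
  expect_equal(pc$counts[i[1], i[3]], 1)
  # 4-cycle: opposite corners have two shortest paths
  g4 <- graph_from_pairs(c("1-2", "2-3", "3-4", "4-1"))
  pc4 <- shortest_path_counts(g4)
  j <- match(c("1", "3"), pc4$nodes)
  expect_equal(pc4$dist[j[1], j[2]], 2)
  expect_equal(pc4$counts[j[1], j[2]], 2)
  # weighted triangle: the 2-hop route (0.3+0.3) beats the direct edge (0.7)
  gt <- graph_from_pairs(c("a-b", "b-c", "a-c"))
  el <- igraph::as_edgelist(gt)
  wts <- ifelse((el[, 1] == "a" & el[, 2] == "c") |
                (el[, 1] == "c" & el[, 2] == "a"), 0.7, 0.3)
  igraph::E(gt)$weight <- wts
  pct <- shortest_path_counts(gt)
  k <- match(c("a", "c"), pct$nodes)
  expect_equal(pct$dist[k[1], k[2]], 0.6)
  expect_equal(pct$counts[k[1], k[2]], 1)
})

test_that("worked betweenness values: star and path graphs", {
  star <- graph_from_pairs(c("c-l1", "c-l2", "c-l3", "c-l4"))
  bstar <- graph_betweenness(star)
  expect_equal(bstar$betweenness[bstar$node == "c"], 1.0)
  expect_equal(bstar$betweenness[bstar$node != "c"], rep(0, 4))
  p5 <- graph_from_pairs(c("1-2", "2-3", "3-4", "4-5"))
  bp <- graph_betweenness(p5)
  expect_equal(bp$betweenness[bp$node == "3"], 4 / 6)
  expect_equal(bp$betweenness[bp$node == "1"], 0)
})

test_that("betweenness matches exhaustive path enumeration on random graphs", {
  for (s in 1:30) {
    n <- sample(5:10, 1)
    g <- random_graph(n, 0.35, weighted = s %% 2 == 0, seed = 1000 + s)
    impl <- graph_betweenness(g)$betweenness
    oracle <- brute_betweenness(g)
    expect_equal(impl, oracle, tolerance = 1e-9,
                 info = sprintf("seed %d (n=%d)", s, n))
  }
})

test_that("betweenness is invariant under node relabeling", {
  g <- random_graph(9, 0.4, weighted = TRUE, seed = 77)
  b1 <- graph_betweenness(g)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  b2 <- graph_betweenness(g2)
  expect_equal(b2$betweenness[match(b1$node, b2$node)], b1$betweenness,
               tolerance = 1e-12)
})

test_that("disconnected graphs normalize per component; tiny components score 0", {
  g <- graph_from_pairs(c("1-2", "2-3", "3-4", "4-5", "x-y"))
  b <- graph_betweenness(g)
  expect_equal(b$betweenness[b$node == "3"], 4 / 6)
  expect_equal(b$component_size[b$node == "x"], 2)
  expect_equal(b$betweenness[b$node %in% c("x", "y")], c(0, 0))
})

test_that("ensemble centrality averages per-snapshot profiles", {
  g1 <- graph_from_pairs(c("a-b", "b-c"), nodes = c("a", "b", "c", "d"))
  g2 <- graph_from_pairs(c("a-b", "b-c", "c-d"), nodes = c("a", "b", "c", "d"))
  egs <- structure(list(graphs = list(g1, g2), n_snapshots = 2,
                        nodes = c("a", "b", "c", "d")),
                   class = "ensemble_graphs")
  ec <- ensemble_centrality(egs)
  p1 <- graph_betweenness(g1); p2 <- graph_betweenness(g2)
  expect_equal(ec$betweenness, (p1$betweenness + p2$betweenness) / 2)
  # identical snapshots reduce to the single-graph profile
  egs2 <- structure(list(graphs = list(g2, g2), n_snapshots = 2,
                         nodes = c("a", "b", "c", "d")),
                    class = "ensemble_graphs")
  expect_equal(ensemble_centrality(egs2)$betweenness, p2$betweenness)
})

test_that("centrality distributions are normalized with the right occupancy", {
  star <- graph_from_pairs(c("c-l1", "c-l2", "c-l3", "c-l4"))
  prof <- graph_betweenness(star)
  d <- centrality_distribution(prof, bins = 10)
  expect_equal(sum(d$prob), 1.0)
  occupied <- d$prob[d$prob > 0]
  expect_equal(sort(occupied), c(1 / 5, 4 / 5))
  flat <- prof; flat$betweenness <- rep(0.3, 5)
  df <- centrality_distribution(flat, bins = 10)
  expect_equal(max(df$prob), 1.0)
})

test_that("cluster averaging validates membership and averages correctly", {
  prof <- structure(data.frame(node = c("a", "b", "c"),
                               betweenness = c(0.2, 0.4, 0.9)),
                    class = c("centrality_profile", "data.frame"))
  cl <- cluster_average_centrality(prof, list(one = "c", two = c("a", "b")))
  expect_equal(cl$mean_betweenness, c(0.9, 0.3))
  expect_error(cluster_average_centrality(prof, list(bad = character())),
               class = "allonet_validation_error")
  expect_error(cluster_average_centrality(prof, list(bad = "zzz")),
               class = "allonet_validation_error")
})

test_that("removing an off-path edge never increases pair multiplicity", {
  g <- graph_from_pairs(c("1-2", "2-3", "3-4", "4-1", "1-5"))
  pc <- shortest_path_counts(g)
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c("1", "5")))
  pc2 <- shortest_path_counts(g2)
  i <- match(c("1", "3"), pc$nodes); i2 <- match(c("1", "3"), pc2$nodes)
  expect_equal(pc2$counts[i2[1], i2[2]], pc$counts[i[1], i[2]])
})
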