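test_that("efficiency and vulnerability match closed forms on named fixtures", {
  p3 <- make_fixture_graph("path3")
  s4 <- make_fixture_graph("star4")
  k5 <- make_fixture_graph("complete", 5)
  r5 <- make_fixture_graph("ring", 5)

  expect_equal(global_efficiency(p3), 5 / 6)
  expect_equal(global_efficiency(s4), 0.75)
  expect_equal(global_efficiency(k5), 1)
  expect_equal(local_efficiency(k5), 1)
  expect_equal(local_efficiency(s4), 0)      # leaf subgraphs trivial, center's edgeless
  expect_equal(local_efficiency(r5), 0)      # ring neighbours are non-adjacent
  expect_equal(betweenness(s4), c(3, 0, 0, 0))
  expect_equal(betweenness(k5), rep(0, 5))
  expect_equal(vulnerability(s4), c(1, rep(-1 / 9, 3)))
  expect_equal(vulnerability(k5), rep(0, 5))
  expect_equal(regional_efficiency(s4), c(1, 2 / 3, 2 / 3, 2 / 3))
  expect_equal(shortest_paths(p3)[1, 3], 2)

  gm <- global_metrics(k5)
  expect_equal(unlist(gm), c(E_glob = 1, E_loc = 1, mean_betweenness = 0, V_glob = 0))
  expect_equal(global_metrics(s4)$V_glob, 1)
})

test_that("distances are infinite across components and BFS matches Floyd-Warshall", {
  two_edges <- binary_network(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                                    c(0, 0, 0, 1), c(0, 0, 1, 0)))
  d <- shortest_paths(two_edges)
  expect_true(all(is.infinite(d[1:2, 3:4])))
  expect_equal(largest_component_size(two_edges), 2)

  set.seed(42)
  for (rep in 1:25) {
    adj <- random_graph(sample(4:12, 1), runif(1, 0.2, 0.7))
    expect_equal(shortest_paths(binary_network(adj)), oracle_floyd_warshall(adj))
  }
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  set.seed(7)
  for (rep in 1:25) {
    adj <- random_graph(sample(4:8, 1), runif(1, 0.25, 0.8))
    expect_equal(betweenness(binary_network(adj)), oracle_betweenness(adj),
                 tolerance = 1e-12)
  }
})

test_that("normalized betweenness has mean one and feeds hub detection", {
  s4 <- make_fixture_graph("star4")
  nb <- normalized_betweenness(betweenness(s4))
  expect_equal(nb, c(4, 0, 0, 0))
  expect_equal(mean(nb), 1)
  expect_equal(identify_hubs(nb), 1L)          # 4 >= 1 + sqrt(3)
  expect_length(identify_hubs(rep(1, 6)), 0)   # sd = 0: nothing stands out
  expect_error(normalized_betweenness(rep(0, 4)), "mean betweenness")

  ring6 <- make_fixture_graph("ring", 6)
  expect_length(identify_hubs(normalized_betweenness(betweenness(ring6))), 0)
})

test_that("mean regional efficiency equals global efficiency", {
  set.seed(11)
  for (rep in 1:10) {
    net <- binary_network(random_graph(10, runif(1, 0.2, 0.8)))
    expect_equal(mean(regional_efficiency(net)), global_efficiency(net))
  }
})

test_that("global efficiency is monotone under edge addition", {
  set.seed(3)
  adj <- random_graph(10, 0.2)
  e0 <- global_efficiency(binary_network(adj))
  off <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
  pick <- off[sample(nrow(off), 3), , drop = FALSE]
  for (k in seq_len(nrow(pick))) {
    adj[pick[k, 1], pick[k, 2]] <- adj[pick[k, 2], pick[k, 1]] <- 1L
    e1 <- global_efficiency(binary_network(adj))
    expect_gte(e1, e0)
    e0 <- e1
  }
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(19)
  adj <- random_graph(9, 0.4)
  perm <- sample(9)
  padj <- adj[perm, perm]
  net <- binary_network(adj)
  pnet <- binary_network(padj)
  expect_equal(betweenness(pnet), betweenness(net)[perm])
  expect_equal(regional_efficiency(pnet), regional_efficiency(net)[perm])
  expect_equal(global_efficiency(pnet), global_efficiency(net))
  expect_equal(local_efficiency(pnet), local_efficiency(net))
})

test_that("betweenness and distances agree with igraph on larger graphs", {
  skip_if_not_installed("igraph")
  set.seed(5)
  adj <- random_graph(40, 0.15)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  net <- binary_network(adj)
  expect_equal(betweenness(net), unname(igraph::betweenness(g)), tolerance = 1e-10)
  d <- igraph::distances(g)
  expect_equal(shortest_paths(net), unname(d))
})

test_that("hub summaries tabulate hemisphere, lobe and group overlap", {
  atlas <- synthetic_atlas(16)
  empty <- summarize_hubs(integer(0), atlas)
  expect_equal(empty$n_hubs, 0)
  expect_true(all(unlist(empty$by_hemisphere) == 0))
  expect_true(all(unlist(empty$by_lobe) == 0))

  left_all <- which(atlas$hemisphere == "left")
  s <- summarize_hubs(left_all, atlas)
  expect_equal(s$by_hemisphere$left, length(left_all))
  expect_equal(s$by_hemisphere$right, 0)

  both <- summarize_hubs(c(1L, 2L, 9L), atlas, c(1L, 2L, 9L))
  expect_length(both$shared, 3)
  expect_length(both$only1, 0)
  expect_length(both$only2, 0)

  diff <- summarize_hubs(c(1L, 2L), atlas, c(2L, 3L))
  expect_equal(diff$shared, atlas$name[2])
  expect_equal(diff$only1, atlas$name[1])
  expect_equal(diff$only2, atlas$name[3])
})
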