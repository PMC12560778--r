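test_that("efficiency matches hand enumeration and the oracle", {
  expect_equal(efficiency(igraph::make_full_graph(5)), 1)
  empty <- igraph::make_empty_graph(4, directed = FALSE)
  expect_equal(efficiency(empty), 0)
  p3 <- igraph::make_ring(3, circular = FALSE)
  expect_equal(efficiency(p3), 5 / 6)
  expect_error(efficiency(igraph::make_empty_graph(1, directed = FALSE)),
               "at least 2")
  for (seed in 1:5) {
    adj <- random_adj(10, 0.3, seed)
    expect_equal(efficiency(graph_from_adj(adj)), efficiency_brute(adj),
                 tolerance = 1e-10)
  }
})

test_that("natural connectivity matches eigen hand cases and expm oracle", {
  k3 <- igraph::make_full_graph(3)
  expect_equal(natural_connectivity(k3), log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-10)
  empty <- igraph::make_empty_graph(5, directed = FALSE)
  expect_equal(natural_connectivity(empty), 0)
  for (seed in 1:5) {
    adj <- random_adj(12, 0.25, seed + 40)
    expect_equal(natural_connectivity(graph_from_adj(adj)),
                 natcon_brute(adj), tolerance = 1e-8)
  }
})

test_that("removal sequences follow their strategies", {
  g <- igraph::make_star(7, mode = "undirected")
  igraph::V(g)$name <- paste0("n", 1:7)
  net <- toy_conet(g, weights = NULL)
  seq_deg <- removal_sequence(net, "node_degree_high", seed = 1)
  expect_equal(seq_deg[1], "n1")  # hub first

  w_g <- igraph::make_ring(4)
  igraph::V(w_g)$name <- paste0("e", 1:4)
  netw <- toy_conet(w_g, weights = c(0.9, 0.5, 0.5, 0.1))
  seq_w <- removal_sequence(netw, "edge_strong", seed = 2)
  expect_equal(seq_w[1], 1)        # strongest edge first
  expect_equal(seq_w[4], 4)        # weakest last
  expect_true(all(sort(seq_w[2:3]) == c(2, 3)))

  expect_error(removal_sequence(net, "nonsense"), "unknown strategy")

  ## hub-free networks give an empty node_hub sequence with a warning
  ring <- toy_conet(igraph::make_ring(6))
  expect_warning(hs <- removal_sequence(ring, "node_hub", seed = 1),
                 "no module hubs")
  expect_length(hs, 0)
})

test_that("node_hub sequences cover exactly the module hubs", {
  ## modular graph with deterministic hubs: each module is a 12-spoke
  ## star with two extra spoke-spoke edges, modules chained by one edge
  blocks <- lapply(0:2, function(b) {
    center <- paste0("m", b, "_c")
    spokes <- paste0("m", b, "_s", 1:12)
    rbind(cbind(center, spokes),
          c(spokes[1], spokes[2]), c(spokes[3], spokes[4]))
  })
  el <- do.call(rbind, blocks)
  el <- rbind(el, c("m0_c", "m1_s5"), c("m1_c", "m2_s5"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  net <- toy_conet(g)
  roles <- zi_pi(net)
  hubs <- roles$taxon_id[roles$role == "module_hub"]
  expect_setequal(hubs, c("m0_c", "m1_c", "m2_c"))
  sq <- removal_sequence(net, "node_hub", seed = 9, roles = roles)
  expect_setequal(sq, hubs)
  expect_length(sq, length(hubs))
})

test_that("robustness curves start at the intact metric and decline", {
  set.seed(8)
  adj <- random_adj(25, 0.2, seed = 8)
  net <- toy_conet(graph_from_adj(adj))
  curves <- robustness_curves(net, strategies = c("edge_rand", "node_rand"),
                              step = 0.1, n_replicates = 5, seed = 3)
  intact_eff <- efficiency(net$graph)
  intact_nc <- natural_connectivity(net$graph)
  at0 <- curves[curves$fraction == 0, ]
  expect_equal(at0$mean[at0$metric == "Eff"], rep(intact_eff, 2),
               tolerance = 1e-12)
  expect_equal(at0$mean[at0$metric == "natural_connectivity"],
               rep(intact_nc, 2), tolerance = 1e-12)
  ## natural connectivity under edge removal is non-increasing
  nc_edge <- curves[curves$strategy == "edge_rand" &
                    curves$metric == "natural_connectivity", ]
  expect_true(all(diff(nc_edge$mean[order(nc_edge$fraction)]) <= 1e-9))
  expect_error(robustness_curves(net, step = 0.7), "step")
})

test_that("natural connectivity strictly decreases under edge deletion", {
  for (seed in 1:50) {
    adj <- random_adj(12, 0.3, seed + 600)
    g <- graph_from_adj(adj)
    if (igraph::ecount(g) == 0) next
    nc0 <- natural_connectivity(g)
    e <- sample(igraph::ecount(g), 1)
    expect_lt(natural_connectivity(igraph::delete_edges(g, e)), nc0)
  }
})

test_that("residual-graph metrics equal metrics on a rebuilt graph", {
  adj <- random_adj(15, 0.3, seed = 77)
  g <- graph_from_adj(adj)
  igraph::V(g)$name <- paste0("n", 1:15)
  drop <- c("n2", "n9", "n14")
  residual <- igraph::delete_vertices(g, drop)
  keep <- setdiff(seq_len(15), c(2, 9, 14))
  rebuilt <- graph_from_adj(adj[keep, keep])
  expect_equal(efficiency(residual), efficiency(rebuilt), tolerance = 1e-12)
  expect_equal(natural_connectivity(residual), natural_connectivity(rebuilt),
               tolerance = 1e-12)
})
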