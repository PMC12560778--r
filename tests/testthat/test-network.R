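test_that("filter_taxa applies the mean relative abundance threshold", {
  ## taxon means straddling the 0.05% cutoff
  counts <- rbind(s1 = c(9990, 4, 5, 1), s2 = c(9990, 6, 5, 0))
  colnames(counts) <- c("big", "at", "exact", "tiny")
  m <- comm_matrix(counts)
  out <- filter_taxa(m, 0.0005)
  rel_means <- colMeans(counts / rowSums(counts))
  expect_setequal(colnames(out), names(rel_means)[rel_means >= 0.0005])
  expect_false("tiny" %in% colnames(out))
  ## threshold 0 is the identity; output taxa always a subset
  expect_equal(colnames(filter_taxa(m, 0)), colnames(m))
  expect_true(all(colnames(out) %in% colnames(m)))
})

test_that("spearman rho equals the rank-then-Pearson oracle with ties", {
  set.seed(4)
  x <- matrix(rpois(60, 3), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:6)))
  x[x == 0] <- 0 # keep ties
  m <- comm_matrix(x + 1)
  edges <- spearman_edges(m, p_thresh = 1.1, q_thresh = 1.1)
  rel <- (x + 1) / rowSums(x + 1)
  for (k in seq_len(nrow(edges))) {
    i <- edges$taxon_1[k]; j <- edges$taxon_2[k]
    expect_equal(edges$rho[k], spearman_brute(rel[, i], rel[, j]),
                 tolerance = 1e-10)
  }
})

test_that("monotone pairs are called and depth rescaling changes nothing", {
  set.seed(9)
  base <- rlnorm(10, 3, 1)
  x <- cbind(a = sort(rlnorm(10)), b = NA, noise = rlnorm(10))
  x[, "b"] <- x[, "a"] * 2 + 0.001
  rownames(x) <- paste0("s", 1:10)
  m <- comm_matrix(x)
  edges <- spearman_edges(m)
  ab <- edges[edges$taxon_1 == "a" & edges$taxon_2 == "b", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$rho, 1)

  scaled <- x * sample(1:9, 10, replace = TRUE)
  e2 <- spearman_edges(comm_matrix(scaled))
  expect_equal(edges$rho, e2$rho, tolerance = 1e-12)
})

test_that("constant columns trigger a warning and are skipped", {
  ## equal row totals keep the constant column constant after
  ## conversion to relative abundance
  set.seed(1)
  a <- sample(10:60, 6)
  x <- cbind(a = a, const = 20, b = 80 - a)
  rownames(x) <- paste0("s", 1:6)
  expect_warning(e <- spearman_edges(comm_matrix(x), p_thresh = 1.1,
                                     q_thresh = 1.1),
                 "constant")
  expect_false("const" %in% c(e$taxon_1, e$taxon_2))
})

test_that("rmt_threshold finds planted block structure and stays in range", {
  set.seed(2)
  n <- 60
  cm <- matrix(0.08, n, n)
  for (b in split(1:n, rep(1:4, each = 15))) cm[b, b] <- 0.8
  cm <- cm + matrix(rnorm(n * n, 0, 0.02), n, n)
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  th <- rmt_threshold(cm)
  expect_lte(as.numeric(th), 0.8)
  expect_gte(as.numeric(th), 0.30)

  ## identity matrix has no transition: upper bound with warning
  expect_warning(th2 <- rmt_threshold(diag(30)), "upper bound")
  expect_equal(as.numeric(th2), 0.9)
})

test_that("module detection recovers planted cliques", {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("n", 1:10)
  mod <- detect_modules(g, seed = 1)
  expect_equal(length(unique(mod$membership)), 2)
  expect_equal(length(unique(mod$membership[1:5])), 1)
  expect_equal(length(unique(mod$membership[6:10])), 1)
  expect_true(mod$modularity >= -0.5 && mod$modularity <= 1)

  ## complete graph collapses to one module with Q ~ 0
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("n", 1:6)
  mk <- detect_modules(k6, seed = 1)
  expect_lte(mk$modularity, 0.05)
  expect_error(detect_modules(igraph::make_empty_graph(3, directed = FALSE)),
               "no edges")
})

test_that("Zi-Pi values match hand computation and roles are equivariant", {
  ## node with k = 4 split evenly across 2 modules -> Pi = 0.5
  g <- igraph::graph_from_edgelist(rbind(
    c("x", "a1"), c("x", "a2"), c("x", "b1"), c("x", "b2"),
    c("a1", "a2"), c("b1", "b2")), directed = FALSE)
  mem <- c(x = 1, a1 = 1, a2 = 1, b1 = 2, b2 = 2)
  roles <- zi_pi(g, mem)
  x_row <- roles[roles$taxon_id == "x", ]
  expect_equal(x_row$pi, 0.5)
  ## all edges within own module -> Pi = 0
  a1 <- roles[roles$taxon_id == "a1", ]
  expect_equal(a1$pi, 0)
  ## degree equal to module mean -> Zi = 0 (a1 and a2 symmetric)
  expect_equal(a1$zi, roles[roles$taxon_id == "a2", "zi"])

  ## node relabelling permutes rows but not role assignments
  perm <- c(x = "n3", a1 = "n5", a2 = "n1", b1 = "n4", b2 = "n2")
  g2 <- g
  igraph::V(g2)$name <- perm[igraph::V(g)$name]
  mem2 <- stats::setNames(mem, perm[names(mem)])
  roles2 <- zi_pi(g2, mem2)
  ord <- match(perm[roles$taxon_id], roles2$taxon_id)
  expect_equal(roles$zi, roles2$zi[ord])
  expect_equal(roles$pi, roles2$pi[ord])
  expect_equal(roles$role, roles2$role[ord])
})

test_that("topology matches hand-computed values on canonical graphs", {
  p3 <- toy_conet(igraph::make_ring(3, circular = FALSE))
  tp <- topology(p3)
  expect_equal(tp$diameter, 2)
  expect_equal(tp$average_degree, 4 / 3)

  k4 <- toy_conet(igraph::make_full_graph(4))
  tk <- topology(k4)
  expect_equal(tk$density, 1)
  expect_equal(tk$clustering_coefficient, 1)
  expect_equal(tk$centralization, 0)

  star <- toy_conet(igraph::make_star(6, mode = "undirected"))
  ts <- topology(star)
  expect_equal(ts$centralization, 1)
  expect_equal(ts$density, 2 * 5 / (6 * 5))
  ## heterogeneity = cv of degree
  deg <- c(5, rep(1, 5))
  expect_equal(ts$heterogeneity, sd(deg) / mean(deg))
})

test_that("network comparison equals explicit set algebra", {
  g1 <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c"),
                                          c("c", "d")), directed = FALSE)
  g2 <- igraph::graph_from_edgelist(rbind(c("b", "a"), c("c", "e")),
                                    directed = FALSE)
  nets <- list(one = toy_conet(g1), two = toy_conet(g2))
  cmp <- compare_networks(nets)
  expect_equal(cmp$shared$shared_nodes, 3)   # a, b, c
  expect_equal(cmp$shared$shared_edges, 1)   # a-b (order-insensitive)
  expect_equal(cmp$unique$unique_nodes, c(1, 1))  # d; e
  expect_equal(cmp$unique$unique_edges, c(2, 1))
  ## identical networks: everything shared, nothing unique
  cmp2 <- compare_networks(list(x = toy_conet(g1), y = toy_conet(g1)))
  expect_equal(cmp2$unique$unique_nodes, c(0, 0))
  expect_equal(cmp2$shared$shared_edges, 3)
  ## disjoint node sets share nothing
  g3 <- igraph::graph_from_edgelist(rbind(c("p", "q")), directed = FALSE)
  cmp3 <- compare_networks(list(x = toy_conet(g1), y = toy_conet(g3)))
  expect_equal(cmp3$shared$shared_nodes, 0)
})

test_that("build_network assembles a consistent conet object", {
  sim <- simulate_metacommunity(sim_params(n_taxa = 80, n_per_group = 2,
                                           seed = 21))
  net <- suppressWarnings(build_network(sim$counts, min_mean_rel = 0.001,
                                        p_thresh = 0.05, q_thresh = 0.2,
                                        seed = 1))
  expect_s3_class(net, "conet")
  expect_true(all(net$edges$weight > 0 & net$edges$weight <= 1))
  expect_true(all(net$edges$taxon_1 != net$edges$taxon_2))
  expect_setequal(names(net$membership), igraph::V(net$graph)$name)
  ## density consistency against the topology table
  tp <- topology(net)
  v <- tp$vertices; e <- tp$edges
  expect_equal(tp$density, 2 * e / (v * (v - 1)))
})

test_that("false edge rate on independent noise stays at the FDR level", {
  fracs <- vapply(1:10, function(seed) {
    set.seed(seed + 900)
    x <- matrix(rlnorm(30 * 60), 30, 60,
                dimnames = list(paste0("s", 1:30), paste0("t", 1:60)))
    e <- spearman_edges(comm_matrix(x), p_thresh = 0.01, q_thresh = 0.05)
    nrow(e) / attr(e, "n_tested")
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})
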