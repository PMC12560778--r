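## Brute-force oracles, written independently of the package internals:
## explicit loops and naive formulas only.

bc_brute <- function(x, y) {
  x <- unname(x); y <- unname(y)
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

## weighted UniFrac by explicit per-branch descendant enumeration
wuf_brute <- function(x, y, tree) {
  px <- x / sum(x); py <- y / sum(y)
  names(px) <- names(py) <- tree$tip.label
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= length(tree$tip.label)) {
      tree$tip.label[child]
    } else {
      ape::extract.clade(tree, child)$tip.label
    }
    pa <- sum(px[tips]); pb <- sum(py[tips])
    num <- num + tree$edge.length[e] * abs(pa - pb)
    den <- den + tree$edge.length[e] * (pa + pb)
  }
  num / den
}

## abundance-weighted beta-MNTD by explicit loops
bmntd_brute <- function(xa, xb, D, weighted = TRUE) {
  xa <- unname(xa); xb <- unname(xb)
  ia <- which(xa > 0); ib <- which(xb > 0)
  wa <- if (weighted) xa[ia] / sum(xa[ia]) else rep(1 / length(ia), length(ia))
  wb <- if (weighted) xb[ib] / sum(xb[ib]) else rep(1 / length(ib), length(ib))
  s1 <- 0
  for (k in seq_along(ia)) {
    mn <- Inf
    for (l in seq_along(ib)) mn <- min(mn, D[ia[k], ib[l]])
    s1 <- s1 + wa[k] * mn
  }
  s2 <- 0
  for (l in seq_along(ib)) {
    mn <- Inf
    for (k in seq_along(ia)) mn <- min(mn, D[ia[k], ib[l]])
    s2 <- s2 + wb[l] * mn
  }
  0.5 * (s1 + s2)
}

chao1_brute <- function(counts) {
  s <- sum(counts > 0)
  f1 <- sum(counts == 1); f2 <- sum(counts == 2)
  if (s == 0) 0 else s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

## one-way PERMANOVA pseudo-F by explicit double loops
permanova_f_brute <- function(dm, labels) {
  n <- nrow(dm)
  ss_t <- 0
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) ss_t <- ss_t + dm[i, j]^2
  ss_t <- ss_t / n
  labels <- as.factor(labels)
  ss_w <- 0
  for (g in levels(labels)) {
    idx <- which(labels == g)
    s <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) {
        for (b in seq((a + 1), length(idx))) s <- s + dm[idx[a], idx[b]]^2
      }
    }
    ss_w <- ss_w + s / length(idx)
  }
  a <- nlevels(labels)
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

## Spearman rho: mid-rank then naive Pearson
spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  num / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

## all-pairs shortest paths by Floyd-Warshall on an adjacency matrix
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

efficiency_brute <- function(adj) {
  d <- floyd_warshall(adj)
  n <- nrow(adj)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
    }
  }
  tot / (n * (n - 1))
}

## natural connectivity through the power series of the matrix
## exponential trace: tr(e^A) = sum_k tr(A^k) / k!
natcon_brute <- function(adj) {
  n <- nrow(adj)
  term <- diag(n)
  tr <- n
  for (k in 1:80) {
    term <- term %*% adj / k
    tr <- tr + sum(diag(term))
  }
  log(tr / n)
}

## fixtures ------------------------------------------------------------

random_comm <- function(n_samples, n_taxa, seed, depth_range = c(50, 200)) {
  set.seed(seed)
  counts <- t(sapply(seq_len(n_samples), function(i) {
    pool <- rlnorm(n_taxa, 0, 1)
    rmultinom(1, sample(depth_range[1]:depth_range[2], 1), pool)[, 1]
  }))
  dimnames(counts) <- list(paste0("s", seq_len(n_samples)),
                           paste0("t", seq_len(n_taxa)))
  comm_matrix(counts)
}

random_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

## minimal conet wrapper for graph-level tests
toy_conet <- function(g, weights = NULL) {
  if (!is.null(weights)) igraph::E(g)$weight <- weights
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g)
  edges <- data.frame(taxon_1 = el[, 1], taxon_2 = el[, 2],
                      rho = igraph::E(g)$weight %||% rep(1, igraph::ecount(g)),
                      sign = "+",
                      weight = igraph::E(g)$weight %||% rep(1, igraph::ecount(g)),
                      p_value = 0, q_value = 0)
  mod <- if (igraph::ecount(g) > 0) detect_modules(g) else
    list(membership = stats::setNames(seq_len(igraph::vcount(g)),
                                      igraph::V(g)$name),
         modularity = NA_real_)
  structure(list(graph = g, edges = edges,
                 nodes = data.frame(taxon_id = igraph::V(g)$name,
                                    mean_rel_abund = 1 / igraph::vcount(g)),
                 membership = mod$membership, modularity = mod$modularity,
                 thresholds = list(), seed = NULL),
            class = "conet")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
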