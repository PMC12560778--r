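#' Average network efficiency
#'
#' \eqn{Eff = \frac{1}{V(V-1)} \sum_{i \ne j} 1/d_{ij}} over ordered
#' node pairs, with unweighted shortest paths and \eqn{1/\infty = 0} for
#' disconnected pairs. 1 for a complete graph, 0 for an empty one.
#'
#' @param g an igraph graph with at least 2 nodes.
#' @return Efficiency in \[0, 1\].
#' @export
efficiency <- function(g) {
  v <- igraph::vcount(g)
  if (v < 2) abort("efficiency needs at least 2 nodes")
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (v * (v - 1))
}

#' Natural connectivity
#'
#' \eqn{\ln\big(\frac{1}{V}\sum_i e^{\lambda_i}\big)} over the
#' eigenvalues of the unweighted adjacency matrix; strictly decreases
#' when any edge is deleted, making it a robustness score.
#'
#' @param g an igraph graph with at least 1 node.
#' @return Natural connectivity (0 for an empty graph).
#' @export
natural_connectivity <- function(g) {
  v <- igraph::vcount(g)
  if (v < 1) abort("graph has no nodes")
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  a[a != 0] <- 1
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  ## log-sum-exp for numerical stability on large spectra
  mx <- max(ev)
  mx + log(mean(exp(ev - mx)))
}

#' Removal sequences for attack simulations
#'
#' Orders nodes or edges for cumulative removal: `edge_rand` /
#' `node_rand` uniformly at random; `edge_strong` by decreasing edge
#' weight (ties randomised); `node_degree_high` by decreasing degree
#' (ties randomised); `node_hub` a random order over module hubs only
#' (empty, with a warning, when the network has none).
#'
#' @param net a `conet`.
#' @param strategy one of `edge_rand`, `edge_strong`, `node_rand`,
#'   `node_degree_high`, `node_hub`.
#' @param seed integer seed.
#' @param roles [zi_pi()] table (required for `node_hub`; computed from
#'   the network when omitted).
#' @return Character vector of node names, or integer vector of edge
#'   ids, with attribute `"kind"` (`"node"`/`"edge"`).
#' @export
removal_sequence <- function(net, strategy, seed = NULL, roles = NULL) {
  strategies <- c("edge_rand", "edge_strong", "node_rand",
                  "node_degree_high", "node_hub")
  if (!strategy %in% strategies)
    abort("unknown strategy '%s'; valid: %s", strategy,
          paste(strategies, collapse = ", "))
  g <- net$graph
  out <- with_seed(seed, switch(strategy,
    edge_rand = sample(seq_len(igraph::ecount(g))),
    edge_strong = {
      w <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
      order(abs(w), runif(length(w)), decreasing = TRUE)
    },
    node_rand = sample(igraph::V(g)$name),
    node_degree_high = {
      deg <- igraph::degree(g)
      igraph::V(g)$name[order(deg, runif(length(deg)), decreasing = TRUE)]
    },
    node_hub = {
      roles <- roles %||% zi_pi(net)
      hubs <- roles$taxon_id[roles$role == "module_hub"]
      if (length(hubs) == 0) {
        warning("network has no module hubs; empty removal sequence")
        character(0)
      } else if (length(hubs) == 1) hubs else sample(hubs)
    }))
  attr(out, "kind") <- if (startsWith(strategy, "edge")) "edge" else "node"
  out
}

#' Attack-tolerance (robustness) curves
#'
#' Removes nodes or edges cumulatively in 10% steps under the chosen
#' strategies, recomputing average efficiency and natural connectivity
#' on the residual graph at each step, averaged over `n_replicates`
#' independent removal orders (tie-break randomisations for the
#' deterministic strategies). For `node_hub` the removal fractions are
#' relative to the hub count.
#'
#' @param net a `conet`.
#' @param strategies character vector of strategies
#'   (see [removal_sequence()]).
#' @param step removal fraction per step, in (0, 0.5].
#' @param n_replicates removal orders averaged per strategy.
#' @param seed integer seed.
#' @param roles optional [zi_pi()] table for `node_hub`.
#' @return Long data.frame: `strategy`, `fraction`, `metric`, `mean`,
#'   `sd`, `n_replicates`.
#' @export
robustness_curves <- function(net, strategies = c("edge_rand", "edge_strong",
                                                  "node_rand",
                                                  "node_degree_high",
                                                  "node_hub"),
                              step = 0.1, n_replicates = 100, seed = NULL,
                              roles = NULL) {
  if (step <= 0 || step > 0.5) abort("step must be in (0, 0.5]")
  g <- net$graph
  fractions <- seq(0, 0.9, by = step)
  rows <- list()
  for (strat in strategies) {
    if (strat == "node_hub" && is.null(roles) && igraph::ecount(g) > 0)
      roles <- zi_pi(net)
    vals_eff <- matrix(NA_real_, n_replicates, length(fractions))
    vals_nc <- matrix(NA_real_, n_replicates, length(fractions))
    for (r in seq_len(n_replicates)) {
      seqr <- removal_sequence(net, strat, seed = derive_seed(seed, r * 101 +
                                                              match(strat, strategies)),
                               roles = roles)
      kind <- attr(seqr, "kind")
      total <- length(seqr)
      for (k in seq_along(fractions)) {
        n_rm <- floor(fractions[k] * total)
        gg <- if (n_rm == 0) g else if (kind == "edge") {
          igraph::delete_edges(g, seqr[seq_len(n_rm)])
        } else {
          igraph::delete_vertices(g, seqr[seq_len(n_rm)])
        }
        vals_eff[r, k] <- if (igraph::vcount(gg) >= 2) efficiency(gg) else 0
        vals_nc[r, k] <- if (igraph::vcount(gg) >= 1)
          natural_connectivity(gg) else 0
      }
    }
    rows[[paste0(strat, "_eff")]] <- data.frame(
      strategy = strat, fraction = fractions, metric = "Eff",
      mean = colMeans(vals_eff), sd = apply(vals_eff, 2, sd),
      n_replicates = n_replicates)
    rows[[paste0(strat, "_nc")]] <- data.frame(
      strategy = strat, fraction = fractions, metric = "natural_connectivity",
      mean = colMeans(vals_nc), sd = apply(vals_nc, 2, sd),
      n_replicates = n_replicates)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
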