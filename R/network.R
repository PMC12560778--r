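#' Abundance filtering for network construction
#'
#' Keeps taxa whose mean relative abundance across samples is at least
#' `min_mean_rel` (default 0.05%), the conventional guard against
#' spurious correlations from extremely rare taxa.
#'
#' @param m a [comm_matrix()].
#' @param min_mean_rel minimum mean relative abundance.
#' @return Filtered [comm_matrix()] (same scale as the input).
#' @export
filter_taxa <- function(m, min_mean_rel = 0.0005) {
  x <- cm_counts(m)
  rel <- if (is_relative(m)) x else {
    rs <- rowSums(x)
    if (any(rs == 0)) abort("zero-sum sample")
    x / rs
  }
  keep <- colMeans(rel) >= min_mean_rel
  if (!any(keep)) abort("no taxon passes the %g abundance filter", min_mean_rel)
  out <- x[, keep, drop = FALSE]
  empty <- rowSums(out) == 0
  if (any(empty)) {
    warning(sprintf("%d sample(s) empty after taxon filtering; dropped",
                    sum(empty)))
    out <- out[!empty, , drop = FALSE]
  }
  if (is_relative(m)) out <- out / rowSums(out)
  comm_matrix(out, is_relative = is_relative(m))
}

#' Spearman co-occurrence edges
#'
#' All taxon pairs are rank-correlated (mid-rank ties); two-sided
#' p-values use the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom, and
#' Benjamini-Hochberg q-values are computed over every tested pair. An
#' edge is kept iff `p < p_thresh` and `q < q_thresh` and
#' `|rho| >= min_rho`. Counts are converted to per-sample relative
#' abundance before ranking, making edge calling invariant to per-sample
#' depth rescaling.
#'
#' @param m a [comm_matrix()] with at least 5 samples.
#' @param p_thresh,q_thresh,min_rho edge-calling thresholds.
#' @return data.frame `taxon_1`, `taxon_2`, `rho`, `sign`, `weight`
#'   (`|rho|`), `p_value`, `q_value`, plus an attribute `n_tested`.
#' @export
spearman_edges <- function(m, p_thresh = 0.01, q_thresh = 0.05, min_rho = 0) {
  x <- cm_counts(to_relative(m))
  n <- nrow(x)
  if (n < 5) abort("rank correlation needs at least 5 samples")
  const <- apply(x, 2, function(col) length(unique(col)) == 1)
  if (any(const)) {
    warning(sprintf("%d constant taxa skipped (correlation undefined)", sum(const)))
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2) abort("fewer than 2 variable taxa")
  rho <- cor(x, method = "spearman")
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  r_c <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_c * sqrt((n - 2) / (1 - r_c^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  q <- p.adjust(p, method = "BH")
  keep <- p < p_thresh & q < q_thresh & abs(r) >= min_rho
  out <- data.frame(
    taxon_1 = colnames(x)[idx[keep, 1]],
    taxon_2 = colnames(x)[idx[keep, 2]],
    rho = r[keep],
    sign = ifelse(r[keep] >= 0, "+", "-"),
    weight = abs(r[keep]),
    p_value = p[keep],
    q_value = q[keep],
    row.names = NULL)
  attr(out, "n_tested") <- length(r)
  out
}

#' Random-matrix-theory correlation threshold
#'
#' Scans absolute-correlation cutoffs (0.30 to 0.90 by 0.01); at each
#' cutoff the thresholded correlation matrix's eigenvalues are unfolded
#' (rank-based spline smoothing of the spectral CDF) and the
#' nearest-neighbour spacing distribution is compared by chi-squared to
#' the Poisson (uncorrelated) and Wigner-Dyson (GOE) forms. Returns the
#' smallest cutoff where Poisson fits better, i.e. where remaining
#' correlations behave like uncoupled modules. If no transition occurs
#' within the scan the upper bound is returned with a warning.
#'
#' @param cor_mat symmetric correlation matrix.
#' @param cutoffs scan grid of candidate thresholds.
#' @return A single cutoff value with attribute `"transition"` (logical).
#' @export
rmt_threshold <- function(cor_mat, cutoffs = seq(0.30, 0.90, by = 0.01)) {
  cm <- as.matrix(cor_mat)
  if (any(abs(cm - t(cm)) > 1e-8)) abort("correlation matrix is not symmetric")
  for (ct in cutoffs) {
    a <- cm
    a[abs(a) < ct] <- 0
    diag(a) <- 1
    ev <- sort(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
    sp <- unfolded_spacings(ev)
    if (length(sp) < 20) next
    fit <- nnsd_fit(sp)
    if (is.finite(fit$poisson) && is.finite(fit$wigner) &&
        fit$poisson < fit$wigner) {
      return(structure(ct, transition = TRUE))
    }
  }
  warning("no Poisson transition within scan range; returning upper bound")
  structure(max(cutoffs), transition = FALSE)
}

## unfold eigenvalues via a smooth estimate of the spectral CDF and
## return nearest-neighbour spacings (mean 1 by construction)
unfolded_spacings <- function(ev) {
  ev <- sort(ev[is.finite(ev)])
  ev <- unique(round(ev, 10))
  n <- length(ev)
  if (n < 10) return(numeric(0))
  cdf <- (seq_len(n) - 0.5) / n
  fit <- stats::smooth.spline(ev, cdf, df = min(10, max(4, n %/% 10)))
  unf <- stats::predict(fit, ev)$y * n
  sp <- diff(unf)
  sp <- sp[sp > 0]
  sp / mean(sp)
}

## chi-squared distances of the spacing histogram to Poisson and GOE
nnsd_fit <- function(sp) {
  brk <- seq(0, max(3, max(sp)), length.out = 16)
  h <- graphics::hist(pmin(sp, max(brk)), breaks = brk, plot = FALSE)
  obs <- h$counts / length(sp)
  mid <- h$mids
  w <- diff(brk)
  pois <- exp(-mid) * w
  wig <- (pi / 2) * mid * exp(-pi * mid^2 / 4) * w
  chisq <- function(e) sum((obs - e)^2 / pmax(e, 1e-6))
  list(poisson = chisq(pois), wigner = chisq(wig))
}

#' Build a co-occurrence network
#'
#' Assembles a `conet` object from a [comm_matrix()]: abundance
#' filtering, [spearman_edges()], optional RMT-optimised minimum
#' correlation, greedy-modularity module detection, and node metadata
#' (mean relative abundance).
#'
#' @param m a [comm_matrix()] (counts or relative abundances).
#' @param min_mean_rel abundance filter threshold.
#' @param p_thresh,q_thresh,min_rho edge thresholds ([spearman_edges()]).
#' @param use_rmt optimise `min_rho` by [rmt_threshold()].
#' @param seed integer seed (module detection).
#' @return A `conet`: list with `graph` (igraph, edge attributes
#'   `weight`, `rho`, `sign`), `edges`, `nodes`, `membership`,
#'   `modularity`, and the thresholds used.
#' @export
build_network <- function(m, min_mean_rel = 0.0005, p_thresh = 0.01,
                          q_thresh = 0.05, min_rho = 0, use_rmt = FALSE,
                          seed = NULL) {
  mf <- filter_taxa(m, min_mean_rel)
  rel <- to_relative(mf)
  if (isTRUE(use_rmt)) {
    x <- cm_counts(mf)
    keep <- apply(x, 2, function(col) length(unique(col)) > 1)
    min_rho <- max(min_rho, as.numeric(rmt_threshold(
      cor(x[, keep, drop = FALSE], method = "spearman"))))
  }
  edges <- spearman_edges(mf, p_thresh, q_thresh, min_rho)
  nodes <- data.frame(taxon_id = colnames(mf),
                      mean_rel_abund = colMeans(cm_counts(rel)))
  g <- igraph::graph_from_data_frame(
    edges[, c("taxon_1", "taxon_2")], directed = FALSE,
    vertices = nodes$taxon_id)
  if (nrow(edges)) {
    igraph::E(g)$weight <- edges$weight
    igraph::E(g)$rho <- edges$rho
    igraph::E(g)$sign <- edges$sign
  }
  mod <- if (igraph::ecount(g) > 0) detect_modules(g, seed = seed) else
    list(membership = setNames(seq_len(igraph::vcount(g)),
                               igraph::V(g)$name), modularity = NA_real_)
  structure(list(graph = g, edges = edges, nodes = nodes,
                 membership = mod$membership, modularity = mod$modularity,
                 thresholds = list(min_mean_rel = min_mean_rel,
                                   p_thresh = p_thresh, q_thresh = q_thresh,
                                   min_rho = min_rho),
                 seed = seed),
            class = "conet")
}

#' @export
print.conet <- function(x, ...) {
  cat(sprintf("conet: %d nodes, %d edges, %d modules, Q = %s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(unique(x$membership)),
              if (is.na(x$modularity)) "NA" else sprintf("%.3f", x$modularity)))
  invisible(x)
}

#' Greedy modularity module detection
#'
#' Fast-greedy modularity maximisation on the unsigned weighted graph.
#' The algorithm is deterministic; `seed` is accepted for interface
#' uniformity with the stochastic stages.
#'
#' @param net a `conet` or igraph graph with at least one edge.
#' @param seed integer seed.
#' @return List with `membership` (named integer vector) and
#'   `modularity` (Q).
#' @export
detect_modules <- function(net, seed = NULL) {
  g <- if (inherits(net, "conet")) net$graph else net
  if (igraph::ecount(g) == 0) abort("graph has no edges")
  cl <- with_seed(seed, igraph::cluster_fast_greedy(
    g, weights = if (is.null(igraph::E(g)$weight)) NULL else igraph::E(g)$weight))
  list(membership = setNames(as.integer(igraph::membership(cl)),
                             igraph::V(g)$name),
       modularity = igraph::modularity(cl))
}

#' Zi-Pi node roles
#'
#' Within-module degree z-score \eqn{Z_i = (k_{i,within} - \bar{k}_m) /
#' sd(k_m)} (0 when the module's within-degree is constant) and
#' among-module connectivity \eqn{P_i = 1 - \sum_s (k_{is}/k_i)^2}.
#' Roles: module hub (Zi > 2.5, Pi <= 0.65), network hub (Zi > 2.5,
#' Pi > 0.65), connector (Zi <= 2.5, Pi > 0.65), peripheral otherwise;
#' isolated nodes are peripheral with Zi = Pi = 0.
#'
#' @param net a `conet`, or an igraph graph plus `membership`.
#' @param membership named module assignment (defaults to the `conet`'s).
#' @return data.frame `taxon_id`, `module`, `degree`, `zi`, `pi`, `role`.
#' @export
zi_pi <- function(net, membership = NULL) {
  g <- if (inherits(net, "conet")) net$graph else net
  membership <- membership %||% if (inherits(net, "conet")) net$membership else
    abort("membership required for a bare graph")
  vn <- igraph::V(g)$name
  if (!all(vn %in% names(membership))) abort("membership must cover all nodes")
  mem <- membership[vn]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- rowSums(adj)
  mods <- sort(unique(mem))
  ## within-module degree per node for each module
  k_is <- sapply(mods, function(md) rowSums(adj[, mem == md, drop = FALSE]))
  if (is.null(dim(k_is))) k_is <- matrix(k_is, nrow = length(vn))
  k_within <- k_is[cbind(seq_along(vn), match(mem, mods))]
  zi <- numeric(length(vn))
  for (md in mods) {
    idx <- mem == md
    mu <- mean(k_within[idx])
    sdv <- sd(k_within[idx])
    zi[idx] <- if (is.na(sdv) || sdv < 1e-12) 0 else (k_within[idx] - mu) / sdv
  }
  pi_v <- ifelse(deg > 0, 1 - rowSums((k_is / pmax(deg, 1))^2), 0)
  role <- ifelse(zi > 2.5 & pi_v <= 0.65, "module_hub",
          ifelse(zi > 2.5 & pi_v > 0.65, "network_hub",
          ifelse(pi_v > 0.65, "connector", "peripheral")))
  data.frame(taxon_id = vn, module = as.integer(mem), degree = deg,
             zi = zi, pi = pi_v, role = role, row.names = NULL)
}

#' Network topology summary
#'
#' Standard topological attributes of a co-occurrence network: vertex
#' and edge counts, average degree (2E/V), density (2E/(V(V-1))),
#' average unweighted shortest-path length and diameter on the largest
#' connected component, mean local clustering coefficient, degree
#' heterogeneity (coefficient of variation of degree), Freeman degree
#' centralization, modularity, and Zi-Pi role counts.
#'
#' @param net a `conet`.
#' @param roles optional precomputed [zi_pi()] table.
#' @return One-row data.frame.
#' @export
topology <- function(net, roles = NULL) {
  g <- net$graph
  v <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (v == 0) abort("empty network")
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  centr <- if (v < 3) {
    warning("centralization undefined for V < 3; reporting 0")
    0
  } else {
    sum(max(deg) - deg) / ((v - 1) * (v - 2))
  }
  roles <- roles %||% if (e > 0) zi_pi(net) else NULL
  data.frame(
    vertices = v,
    edges = e,
    average_degree = 2 * e / v,
    average_path_length = if (igraph::vcount(giant) > 1)
      igraph::mean_distance(giant, weights = NA) else NA_real_,
    diameter = if (igraph::vcount(giant) > 1)
      igraph::diameter(giant, weights = NA) else 0,
    clustering_coefficient = {
      tr <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
      if (is.nan(tr)) 0 else tr
    },
    density = 2 * e / (v * (v - 1)),
    heterogeneity = if (mean(deg) > 0) sd(deg) / mean(deg) else 0,
    centralization = centr,
    modularity = net$modularity,
    module_hubs = if (is.null(roles)) 0L else sum(roles$role == "module_hub"),
    peripheral_nodes = if (is.null(roles)) v else sum(roles$role == "peripheral"))
}

#' Cross-network node and edge sharing
#'
#' Set comparison of two or more networks: per network the nodes and
#' edges unique to it, and pairwise shared counts. Percentages are
#' relative to the total number of node (edge) instances summed over the
#' compared networks (configurable via `denominator = "union"`).
#'
#' @param nets named list of `conet` objects.
#' @param denominator `"instances"` (default) or `"union"`.
#' @return List with data.frames `unique` and `shared`.
#' @export
compare_networks <- function(nets, denominator = c("instances", "union")) {
  denominator <- match.arg(denominator)
  if (length(nets) < 2) abort("need at least 2 networks")
  if (is.null(names(nets))) names(nets) <- paste0("net", seq_along(nets))
  node_sets <- lapply(nets, function(n) igraph::V(n$graph)$name)
  edge_sets <- lapply(nets, function(n) {
    if (nrow(n$edges) == 0) return(character(0))
    apply(cbind(pmin(n$edges$taxon_1, n$edges$taxon_2),
                pmax(n$edges$taxon_1, n$edges$taxon_2)), 1, paste, collapse = "|")
  })
  denom <- function(sets) switch(denominator,
    instances = sum(lengths(sets)),
    union = length(unique(unlist(sets))))
  nd <- denom(node_sets)
  ed <- denom(edge_sets)
  uniq <- do.call(rbind, lapply(names(nets), function(nm) {
    others_n <- unique(unlist(node_sets[setdiff(names(nets), nm)]))
    others_e <- unique(unlist(edge_sets[setdiff(names(nets), nm)]))
    un <- setdiff(node_sets[[nm]], others_n)
    ue <- setdiff(edge_sets[[nm]], others_e)
    data.frame(network = nm,
               unique_nodes = length(un),
               unique_nodes_pct = if (nd > 0) 100 * length(un) / nd else 0,
               unique_edges = length(ue),
               unique_edges_pct = if (ed > 0) 100 * length(ue) / ed else 0)
  }))
  prs <- combn(names(nets), 2)
  shared <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
    a <- prs[1, k]; b <- prs[2, k]
    sn <- intersect(node_sets[[a]], node_sets[[b]])
    se <- intersect(edge_sets[[a]], edge_sets[[b]])
    data.frame(network_1 = a, network_2 = b,
               shared_nodes = length(sn),
               shared_nodes_pct = if (nd > 0) 100 * length(sn) / nd else 0,
               shared_edges = length(se),
               shared_edges_pct = if (ed > 0) 100 * length(se) / ed else 0)
  }))
  list(unique = uniq, shared = shared)
}

#' Key-species (hub) attribute table
#'
#' Per module hub: degree, betweenness, closeness and eigenvector
#' centrality (unweighted graph), mean relative abundance, module and
#' Zi. Empty when the network has no module hubs.
#'
#' @param net a `conet`.
#' @param roles optional precomputed [zi_pi()] table.
#' @return data.frame, one row per module hub.
#' @export
key_species <- function(net, roles = NULL) {
  roles <- roles %||% zi_pi(net)
  hubs <- roles[roles$role == "module_hub", , drop = FALSE]
  g <- net$graph
  if (nrow(hubs) == 0) {
    return(data.frame(taxon_id = character(0), degree = numeric(0),
                      betweenness = numeric(0), closeness = numeric(0),
                      eigenvector = numeric(0), abundance = numeric(0),
                      module = integer(0), z_value = numeric(0)))
  }
  btw <- igraph::betweenness(g, v = hubs$taxon_id, weights = NA)
  cls <- suppressWarnings(igraph::closeness(g, v = hubs$taxon_id, weights = NA))
  eig <- igraph::eigen_centrality(g, weights = NA)$vector[hubs$taxon_id]
  ab <- net$nodes$mean_rel_abund[match(hubs$taxon_id, net$nodes$taxon_id)]
  data.frame(taxon_id = hubs$taxon_id, degree = hubs$degree,
             betweenness = btw, closeness = cls, eigenvector = eig,
             abundance = ab, module = hubs$module, z_value = hubs$zi,
             row.names = NULL)
}
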