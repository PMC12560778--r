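#' Between-community mean nearest taxon distance (beta-MNTD)
#'
#' For communities A and B with within-community relative abundances f
#' and patristic distances D on the community phylogeny,
#' \deqn{\beta MNTD = \tfrac{1}{2}\Big[\sum_{i \in A} f_{iA}
#'   \min_{j \in B} D_{ij} + \sum_{j \in B} f_{jB} \min_{i \in A}
#'   D_{ij}\Big].}
#' Unweighted mode gives every present taxon equal weight.
#'
#' @param m a [comm_matrix()]; all taxa with nonzero counts must be tips
#'   of `tree`.
#' @param tree rooted `phylo` tree with branch lengths.
#' @param abundance_weighted weight taxa by relative abundance (default).
#' @return A `dist` of beta-MNTD values.
#' @export
beta_mntd <- function(m, tree, abundance_weighted = TRUE) {
  prep <- assembly_prep(m, tree)
  bm <- cpp_beta_mntd(prep$D, prep$W, abundance_weighted)
  dimnames(bm) <- list(rownames(m), rownames(m))
  stats::as.dist(bm)
}

## validates matrix/tree correspondence; returns distance matrix ordered
## like the community matrix columns
assembly_prep <- function(m, tree) {
  x <- cm_counts(m)
  if (any(rowSums(x) == 0)) abort("sample with zero taxa")
  present <- colnames(x)[colSums(x) > 0]
  unknown <- setdiff(present, tree$tip.label)
  if (length(unknown))
    abort("taxa not in tree: %s", paste(head(unknown, 5), collapse = ", "))
  sub <- ape::keep.tip(tree, intersect(tree$tip.label, colnames(x)))
  D <- ape::cophenetic.phylo(sub)
  ## taxa absent from the tree must have zero counts; keep matrix columns
  ## restricted to tree tips so D and W align
  keep <- colnames(x) %in% sub$tip.label
  W <- x[, keep, drop = FALSE]
  D <- D[colnames(W), colnames(W)]
  list(D = D, W = W)
}

#' beta-nearest taxon index (beta-NTI)
#'
#' Standardised effect size of [beta_mntd()] against a null that shuffles
#' taxon labels across the tips of the phylogeny (the standard
#' taxa-shuffle null): \eqn{\beta NTI = (obs - \bar{null}) / sd(null)}
#' per sample pair. Pairs whose null distribution is degenerate
#' (`sd = 0`, e.g. on a star phylogeny) get beta-NTI 0. Values above +2
#' indicate variable selection, below -2 homogeneous selection.
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip shuffles (>= 99).
#' @param seed integer seed.
#' @return Symmetric matrix of z-scores with a `"beta_mntd_obs"`
#'   attribute holding the observed beta-MNTD `dist`.
#' @export
beta_nti <- function(m, tree, n_null = 999, seed = NULL,
                     abundance_weighted = TRUE) {
  if (n_null < 99) abort("n_null must be at least 99 for a stable z-score")
  prep <- assembly_prep(m, tree)
  n_taxa <- ncol(prep$W)
  perms <- with_seed(seed, t(replicate(n_null, sample.int(n_taxa))))
  res <- cpp_beta_nti(prep$D, prep$W, abundance_weighted, perms)
  z <- (res$obs - res$null_mean) / res$null_sd
  z[res$null_sd < 1e-12] <- 0
  diag(z) <- 0
  dimnames(z) <- list(rownames(m), rownames(m))
  obs <- res$obs
  dimnames(obs) <- dimnames(z)
  attr(z, "beta_mntd_obs") <- stats::as.dist(obs)
  z
}

#' Raup-Crick dissimilarity on Bray-Curtis (RC-Bray)
#'
#' Null-model standardised Bray-Curtis following the Stegen null: for
#' each sample, a null community keeps the observed richness (taxa drawn
#' with probability proportional to regional occurrence frequency, each
#' seeded with one read) and the observed read total (remaining reads
#' allocated multinomially with probability proportional to regional
#' relative abundance). Per pair,
#' \deqn{RC = 2\,[\#(null < obs) + 0.5\,\#(null = obs)] / n_{null} - 1,}
#' bounded in \[-1, 1\]. RC > 0.95 indicates communities more dissimilar
#' than expected (dispersal limitation), RC < -0.95 more similar
#' (homogenizing dispersal).
#'
#' @param m a [comm_matrix()] of integer counts (typically rarefied).
#' @param n_null number of randomisations.
#' @param seed integer seed.
#' @return Symmetric matrix of RC values in \[-1, 1\].
#' @export
raup_crick_bray <- function(m, n_null = 1000, seed = NULL) {
  x <- cm_counts(m)
  if (!is_count_matrix(x)) abort("raup_crick_bray expects integer counts")
  x <- round(x)
  if (nrow(x) < 2) abort("need at least 2 samples")
  if (any(rowSums(x) == 0)) abort("sample with zero total reads")
  ## canonical internal ordering by ids so results under a fixed seed do
  ## not depend on the input's row or column order
  in_order <- rownames(x)
  x <- x[order(rownames(x)), order(colnames(x)), drop = FALSE]
  n <- nrow(x)
  n_taxa <- ncol(x)
  occ <- colSums(x > 0)
  reg <- colSums(x) / sum(x)
  rich <- rowSums(x > 0)
  depth <- rowSums(x)
  obs <- as.matrix(vegan::vegdist(x, method = "bray"))
  lt <- matrix(0, n, n)
  eq <- matrix(0, n, n)
  candidates <- which(occ > 0)
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      nullm <- matrix(0, n, n_taxa)
      for (s in seq_len(n)) {
        S <- rich[s]
        idx <- if (length(candidates) == 1) candidates else
          sample(candidates, S, prob = occ[candidates])
        nullm[s, idx] <- 1
        extra <- depth[s] - S
        if (extra > 0) {
          p <- reg[idx]
          if (sum(p) == 0) p <- rep(1, length(idx))
          nullm[s, idx] <- nullm[s, idx] + rmultinom(1, extra, p)[, 1]
        }
      }
      bc <- as.matrix(vegan::vegdist(nullm, method = "bray"))
      lt <- lt + (bc < obs - 1e-12)
      eq <- eq + (abs(bc - obs) <= 1e-12)
    }
  })
  rc <- 2 * (lt + 0.5 * eq) / n_null - 1
  diag(rc) <- 0
  dimnames(rc) <- list(rownames(x), rownames(x))
  rc[in_order, in_order]
}

#' Five-way assembly process classification
#'
#' Deterministic mapping of (beta-NTI, RC-Bray) pairs to assembly
#' processes: beta-NTI > 2 is variable selection, < -2 homogeneous
#' selection; otherwise RC-Bray > 0.95 is dispersal limitation, < -0.95
#' homogenizing dispersal, and the remainder (including the exact
#' threshold boundaries) is ecological drift.
#'
#' @param beta_nti numeric vector of beta-NTI z-scores.
#' @param rc_bray numeric vector of RC-Bray values (recycled pairwise).
#' @return Factor with levels `variable_selection`,
#'   `homogeneous_selection`, `dispersal_limitation`,
#'   `homogenizing_dispersal`, `drift`.
#' @export
classify_processes <- function(beta_nti, rc_bray) {
  if (length(beta_nti) != length(rc_bray))
    abort("beta_nti and rc_bray must have equal length")
  if (any(!is.finite(beta_nti)) || any(!is.finite(rc_bray)))
    abort("non-finite beta_nti or rc_bray")
  out <- rep("drift", length(beta_nti))
  out[beta_nti > 2] <- "variable_selection"
  out[beta_nti < -2] <- "homogeneous_selection"
  sto <- abs(beta_nti) <= 2
  out[sto & rc_bray > 0.95] <- "dispersal_limitation"
  out[sto & rc_bray < -0.95] <- "homogenizing_dispersal"
  factor(out, levels = assembly_processes())
}

#' @rdname classify_processes
#' @export
assembly_processes <- function() {
  c("variable_selection", "homogeneous_selection",
    "dispersal_limitation", "homogenizing_dispersal", "drift")
}

#' Pairwise assembly inference and process fractions
#'
#' `assembly_pairs()` runs [beta_nti()] and [raup_crick_bray()] on one
#' community matrix and classifies every sample pair.
#' `process_fractions()` tabulates, per habitat group, the percentage of
#' within-group pairs assigned to each process (columns sum to 100).
#'
#' @inheritParams beta_mntd
#' @param n_null_bnti,n_null_rc null sizes for the two null models.
#' @param seed integer seed.
#' @return `assembly_pairs()`: data.frame with one row per sample pair
#'   (`sample_i`, `sample_j`, `beta_mntd_obs`, `beta_nti`, `rc_bray`,
#'   `process`).
#' @export
assembly_pairs <- function(m, tree, n_null_bnti = 999, n_null_rc = 1000,
                           seed = NULL, abundance_weighted = TRUE) {
  z <- beta_nti(m, tree, n_null = n_null_bnti,
                seed = derive_seed(seed, 1),
                abundance_weighted = abundance_weighted)
  rc <- raup_crick_bray(m, n_null = n_null_rc, seed = derive_seed(seed, 2))
  obs <- as.matrix(attr(z, "beta_mntd_obs"))
  idx <- which(upper.tri(z), arr.ind = TRUE)
  data.frame(
    sample_i = rownames(z)[idx[, 1]],
    sample_j = colnames(z)[idx[, 2]],
    beta_mntd_obs = obs[idx],
    beta_nti = z[idx],
    rc_bray = rc[idx],
    process = classify_processes(z[idx], rc[idx]),
    row.names = NULL)
}

#' @rdname assembly_pairs
#' @param pairs data.frame from `assembly_pairs()`.
#' @param groups named vector mapping sample ids to habitat groups.
#' @return `process_fractions()`: data.frame with processes in rows, one
#'   column per group (percentages), plus an `n_samples` attribute.
#' @export
process_fractions <- function(pairs, groups) {
  gi <- groups[pairs$sample_i]
  gj <- groups[pairs$sample_j]
  within <- !is.na(gi) & !is.na(gj) & gi == gj
  glev <- unique(groups[!is.na(groups)])
  cols <- list()
  n_samp <- integer(0)
  for (g in glev) {
    if (sum(groups == g, na.rm = TRUE) < 2) {
      warning(sprintf("group '%s' has fewer than 2 samples; column omitted", g))
      next
    }
    sel <- within & gi == g
    tab <- table(factor(pairs$process[sel], levels = assembly_processes()))
    cols[[g]] <- as.vector(tab) / sum(tab) * 100
    n_samp[g] <- sum(groups == g, na.rm = TRUE)
  }
  out <- data.frame(process = assembly_processes(), cols, check.names = FALSE)
  attr(out, "n_samples") <- n_samp
  out
}
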