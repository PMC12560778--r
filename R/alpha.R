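#' Alpha diversity indices
#'
#' Hill-number style alpha diversity for a single sample: observed
#' richness, bias-corrected Chao1, the exponential of Shannon entropy
#' (Hill order 1), inverse Simpson concentration (Hill order 2), and
#' Faith phylogenetic diversity. [alpha_diversity()] assembles the
#' per-sample table used downstream.
#'
#' Chao1 uses the bias-corrected form
#' \deqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}
#' with \eqn{F_1}, \eqn{F_2} the singleton and doubleton counts, so the
#' estimate is defined even when no doubletons are observed.
#'
#' @param counts non-negative integer count vector for one sample.
#' @param rel vector of proportions summing to one.
#' @return A single number; [alpha_diversity()] returns a data.frame with
#'   one row per sample.
#' @examples
#' chao1(c(5, 3, 1, 1, 1, 1, 2, 2, 9, 4))
#' hill_shannon(c(0.8, 0.2))
#' @export
chao1 <- function(counts) {
  if (any(abs(counts - round(counts)) > 1e-8))
    abort("chao1 requires integer counts, not proportions")
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  if (s_obs == 0) return(0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname chao1
#' @export
hill_shannon <- function(rel) {
  rel <- check_rel(rel)
  p <- rel[rel > 0]
  exp(-sum(p * log(p)))
}

#' @rdname chao1
#' @export
hill_simpson <- function(rel) {
  rel <- check_rel(rel)
  1 / sum(rel^2)
}

check_rel <- function(rel) {
  if (sum(rel) <= 0) abort("zero-sum abundance vector")
  if (any(rel < 0)) abort("negative abundances")
  rel / sum(rel)
}

#' Faith phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting the present
#' taxa to the root of `tree`.
#'
#' @param present_taxa character vector of tip labels present in the
#'   sample (duplicates ignored).
#' @param tree a rooted `phylo` tree with branch lengths.
#' @return Total branch length; 0 for an empty set.
#' @export
faith_pd <- function(present_taxa, tree) {
  present_taxa <- unique(present_taxa)
  if (length(present_taxa) == 0) return(0)
  unknown <- setdiff(present_taxa, tree$tip.label)
  if (length(unknown))
    abort("taxa not in tree: %s", paste(head(unknown, 5), collapse = ", "))
  n_tip <- length(tree$tip.label)
  tips <- match(present_taxa, tree$tip.label)
  ## walk root-ward from each present tip, marking used edges
  parent_of <- integer(max(tree$edge))
  edge_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  used <- logical(nrow(tree$edge))
  for (tip in tips) {
    node <- tip
    while (parent_of[node] != 0 && !used[edge_of[node]]) {
      used[edge_of[node]] <- TRUE
      node <- parent_of[node]
    }
  }
  sum(tree$edge.length[used])
}

#' @rdname chao1
#' @param m a [comm_matrix()] of read counts.
#' @param tree optional `phylo` tree for Faith PD (skipped when `NULL`).
#' @export
alpha_diversity <- function(m, tree = NULL) {
  x <- cm_counts(m)
  is_rel <- is_relative(m)
  res <- data.frame(
    sample_id = rownames(x),
    s_obs = rowSums(x > 0),
    chao1 = if (is_rel) NA_real_ else apply(x, 1, chao1),
    hill_shannon = apply(x, 1, hill_shannon),
    hill_simpson = apply(x, 1, hill_simpson),
    row.names = NULL
  )
  if (!is.null(tree)) {
    res$faith_pd <- apply(x, 1, function(row) {
      faith_pd(colnames(x)[row > 0], tree)
    })
  }
  res
}
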