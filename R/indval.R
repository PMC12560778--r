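#' Indicator species analysis (IndVal)
#'
#' Dufrene-Legendre indicator values for every taxon against a sample
#' grouping (typically host species). For taxon t and group g,
#' specificity \eqn{A_{tg}} is the mean relative abundance of t in g
#' divided by the summed mean abundance across groups, fidelity
#' \eqn{B_{tg}} is the fraction of group-g samples containing t, and
#' \eqn{IndVal_t = \max_g A_{tg} B_{tg}} (0-1 scale). Significance is a
#' group-label permutation test with the add-one convention; taxa with
#' \eqn{p \le alpha} are flagged as group-specific indicators.
#'
#' Abundances are converted to per-sample relative abundance before
#' computing A (set `relativize = FALSE` for raw-count mode), which makes
#' the index invariant to per-sample sequencing depth. Ties in the best
#' group are broken toward the earlier factor level.
#'
#' @param m a [comm_matrix()].
#' @param groups grouping vector (one label per sample).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param alpha significance level used for the `indicator` flag.
#' @param relativize convert rows to proportions first (default `TRUE`).
#' @return data.frame: `taxon_id`, `group` (best group), `A`, `B`,
#'   `indval`, `p_value`, `indicator`.
#' @export
indval <- function(m, groups, n_perm = 1000, seed = NULL, alpha = 0.01,
                   relativize = TRUE) {
  groups <- as.factor(groups)
  if (length(groups) != nrow(m)) abort("groups must match sample count")
  if (nlevels(droplevels(groups)) < 2) abort("need at least 2 groups")
  if (any(table(droplevels(groups)) == 0)) abort("empty group")
  x <- cm_counts(m)
  if (relativize && !is_relative(m)) {
    rs <- rowSums(x)
    if (any(rs == 0)) abort("zero-sum sample; drop it before indval")
    x <- x / rs
  }
  obs <- indval_stat(x, groups)
  ge <- with_seed(seed, {
    cnt <- numeric(ncol(x))
    for (i in seq_len(n_perm)) {
      perm <- indval_stat(x, sample(groups), values_only = TRUE)
      cnt <- cnt + (perm >= obs$indval - 1e-12)
    }
    cnt
  })
  p <- (1 + ge) / (n_perm + 1)
  p[obs$indval == 0] <- 1
  data.frame(taxon_id = colnames(x),
             group = obs$group,
             A = obs$A, B = obs$B, indval = obs$indval,
             p_value = p,
             indicator = p <= alpha & obs$indval > 0,
             row.names = NULL)
}

## core IndVal computation; x is samples x taxa (already relativized)
indval_stat <- function(x, groups, values_only = FALSE) {
  groups <- droplevels(groups)
  g_mean <- rowsum(x, groups) / as.vector(table(groups))      # groups x taxa
  g_occ <- rowsum((x > 0) * 1, groups) / as.vector(table(groups))
  tot <- colSums(g_mean)
  a <- sweep(g_mean, 2, ifelse(tot > 0, tot, 1), "/")
  a[, tot == 0] <- 0
  iv <- a * g_occ
  best <- apply(iv, 2, which.max)                             # first max wins
  vals <- iv[cbind(best, seq_len(ncol(x)))]
  if (values_only) return(vals)
  list(group = rownames(iv)[best],
       A = a[cbind(best, seq_len(ncol(x)))],
       B = g_occ[cbind(best, seq_len(ncol(x)))],
       indval = vals)
}
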