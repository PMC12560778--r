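#' Community cohesion
#'
#' Cohesion quantifies how strongly a sample's taxa co-vary with the
#' rest of the community. Pairwise Pearson correlations between taxa are
#' corrected by a taxon-shuffle null (observed minus the mean
#' correlation after independently permuting the partner taxon's
#' abundances across samples). Each taxon's positive (negative)
#' connectedness \eqn{c_t^+} (\eqn{c_t^-}) is the mean of its positive
#' (negative) corrected correlations with all other taxa, and per-sample
#' cohesion is abundance-weighted:
#' \deqn{C^\pm_s = \sum_t r_{st}\, c_t^\pm,}
#' so \eqn{C^+ \ge 0} and \eqn{C^- \le 0} always.
#'
#' @param m a [comm_matrix()]; converted to relative abundance
#'   internally.
#' @param n_null number of taxon-shuffle permutations.
#' @param seed integer seed.
#' @param groups optional sample grouping; when given, group differences
#'   in C+ and C- are assessed by a label-permutation test on the
#'   difference of group means.
#' @param n_perm permutations for the group test.
#' @return List with `connectedness` (per taxon `c_pos`, `c_neg`),
#'   `samples` (per sample `cohesion_pos`, `cohesion_neg`), and when
#'   `groups` is given a `group_test` data.frame.
#' @export
cohesion <- function(m, n_null = 200, seed = NULL, groups = NULL,
                     n_perm = 999) {
  if (nrow(m) < 5) abort("cohesion needs at least 5 samples")
  rel <- cm_counts(to_relative(m))
  keep <- apply(rel, 2, function(col) sd(col) > 0)
  x <- rel[, keep, drop = FALSE]
  nt <- ncol(x)
  obs_cor <- cor(x)
  null_mean <- with_seed(seed, {
    acc <- matrix(0, nt, nt)
    for (r in seq_len(n_null)) {
      xs <- apply(x, 2, sample)
      acc <- acc + cor(x, xs)
    }
    ## cor(x_i, shuffled x_j) estimates the null for the (i, j) pair;
    ## symmetrise since the shuffle is one-sided
    acc <- acc / n_null
    (acc + t(acc)) / 2
  })
  corrected <- obs_cor - null_mean
  diag(corrected) <- 0
  c_pos <- apply(corrected, 1, function(row) {
    v <- row[row > 0]
    if (length(v)) sum(v) / (nt - 1) else 0
  })
  c_neg <- apply(corrected, 1, function(row) {
    v <- row[row < 0]
    if (length(v)) sum(v) / (nt - 1) else 0
  })
  coh_pos <- as.vector(x %*% c_pos)
  coh_neg <- as.vector(x %*% c_neg)
  out <- list(
    connectedness = data.frame(taxon_id = colnames(x),
                               c_pos = c_pos, c_neg = c_neg,
                               row.names = NULL),
    samples = data.frame(sample_id = rownames(x),
                         cohesion_pos = coh_pos, cohesion_neg = coh_neg,
                         row.names = NULL))
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (length(groups) != nrow(x)) abort("groups must match sample count")
    out$group_test <- rbind(
      cohesion_perm_test(coh_pos, groups, n_perm, derive_seed(seed, 11), "positive"),
      cohesion_perm_test(coh_neg, groups, n_perm, derive_seed(seed, 12), "negative"))
  }
  out
}

cohesion_perm_test <- function(y, groups, n_perm, seed, label) {
  gm <- tapply(y, groups, mean)
  obs <- max(gm) - min(gm)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pg <- sample(groups)
    pm <- tapply(y, pg, mean)
    max(pm) - min(pm)
  }, numeric(1)))
  data.frame(metric = label, statistic = obs,
             p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
             n_perm = n_perm, row.names = NULL)
}
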