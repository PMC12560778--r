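#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a dissimilarity matrix. With
#' \eqn{SS_T = \frac{1}{N}\sum_{i<j} d_{ij}^2} and
#' \eqn{SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2}, the
#' pseudo-F is \eqn{(SS_A/(a-1)) / (SS_W/(N-a))} with
#' \eqn{SS_A = SS_T - SS_W}. The p-value counts permuted statistics at
#' least as large as the observed one with the add-one convention
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (n_{perm} + 1)}.
#'
#' For two crossed factors, `permanova2()` reports marginal tests via
#' [vegan::adonis2()] with `by = "margin"`.
#'
#' @param d `dist` object or symmetric dissimilarity matrix.
#' @param labels grouping vector, one entry per sample, in `d` order.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutation stream.
#' @return data.frame of class `perm_test` with `statistic`, `r2`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = NULL) {
  dm <- as.matrix(d)
  labels <- as.factor(labels)
  if (length(labels) != nrow(dm)) abort("labels must match sample count")
  if (nlevels(droplevels(labels)) < 2) abort("need at least 2 groups")
  if (any(table(labels) < 2)) abort("every group needs at least 2 samples")
  obs <- permanova_stat(dm, labels)
  perm_f <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    permanova_stat(dm, sample(labels))$f
  }, numeric(1)))
  p <- (1 + sum(perm_f >= obs$f)) / (n_perm + 1)
  structure(
    data.frame(statistic = obs$f, r2 = obs$r2, p_value = p,
               n_perm = n_perm, seed = seed %||% NA_integer_),
    class = c("perm_test", "data.frame"))
}

permanova_stat <- function(dm, labels) {
  n <- nrow(dm)
  a <- nlevels(droplevels(labels))
  d2 <- dm^2
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in levels(droplevels(labels))) {
    idx <- which(labels == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_a <- ss_t - ss_w
  f <- (ss_a / (a - 1)) / (ss_w / (n - a))
  list(f = f, r2 = ss_a / ss_t)
}

#' @rdname permanova
#' @export
permanova_pairwise <- function(d, labels, n_perm = 999, seed = NULL) {
  labels <- as.factor(labels)
  lev <- levels(droplevels(labels))
  prs <- combn(lev, 2)
  dm <- as.matrix(d)
  out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
    keep <- labels %in% prs[, k]
    res <- permanova(dm[keep, keep], droplevels(labels[keep]),
                     n_perm = n_perm, seed = derive_seed(seed, k))
    data.frame(group1 = prs[1, k], group2 = prs[2, k], res)
  }))
  ## Bonferroni over the family of pairwise tests
  out$p_adjusted <- pmin(1, out$p_value * ncol(prs))
  out
}

#' @rdname permanova
#' @param data data.frame holding the factor columns named in `formula`.
#' @param formula right-hand-side formula of factors, e.g. `~ host + habitat`.
#' @export
permanova2 <- function(d, data, formula, n_perm = 999, seed = NULL) {
  fml <- stats::as.formula(paste("d ~", paste(all.vars(formula), collapse = " + ")))
  env <- list2env(list(d = stats::as.dist(d)))
  for (v in all.vars(formula)) assign(v, data[[v]], envir = env)
  environment(fml) <- env
  res <- with_seed(seed, vegan::adonis2(fml, data = data,
                                        permutations = n_perm, by = "margin"))
  data.frame(term = rownames(res), statistic = res$F, r2 = res$R2,
             p_value = res$`Pr(>F)`, n_perm = n_perm,
             seed = seed %||% NA_integer_, row.names = NULL)
}

#' Homogeneity of multivariate dispersion (PERMDISP)
#'
#' Tests equality of group dispersions: each sample's distance to its
#' group centroid is measured in principal-coordinate space (components
#' on negative-eigenvalue axes are subtracted in squared distance, as in
#' PERMDISP2), an ANOVA F statistic is computed on those distances, and
#' significance comes from permuting least-squares residuals across
#' groups.
#'
#' @inheritParams permanova
#' @return A `perm_test` data.frame (R2 from the dispersion ANOVA).
#' @export
permdisp <- function(d, labels, n_perm = 999, seed = NULL) {
  dm <- as.matrix(d)
  labels <- as.factor(labels)
  if (length(labels) != nrow(dm)) abort("labels must match sample count")
  if (nlevels(droplevels(labels)) < 2) abort("need at least 2 groups")
  if (any(table(labels) < 2)) abort("every group needs at least 2 samples")
  z <- centroid_distances(dm, labels)
  obs <- dispersion_f(z, labels)
  ## permute least-squares residuals: under the null of equal dispersion
  ## the group assignment of residuals is exchangeable
  resid <- z - tapply(z, labels, mean)[labels]
  perm_f <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    dispersion_f(sample(resid), labels)$f
  }, numeric(1)))
  p <- (1 + sum(perm_f >= obs$f)) / (n_perm + 1)
  structure(
    data.frame(statistic = obs$f, r2 = obs$r2, p_value = p,
               n_perm = n_perm, seed = seed %||% NA_integer_),
    class = c("perm_test", "data.frame"))
}

## distance of each sample to its group centroid in PCoA space, handling
## imaginary axes by subtracting their squared components
centroid_distances <- function(dm, labels) {
  n <- nrow(dm)
  a <- -0.5 * dm^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  keep <- abs(eig$values) > max(abs(eig$values)) * 1e-10
  vals <- eig$values[keep]
  vecs <- eig$vectors[, keep, drop = FALSE]
  coords <- vecs %*% diag(sqrt(abs(vals)), length(vals), length(vals))
  pos <- vals > 0
  z2 <- numeric(n)
  for (gl in levels(droplevels(labels))) {
    idx <- which(labels == gl)
    cen <- colMeans(coords[idx, , drop = FALSE])
    dif2 <- sweep(coords[idx, , drop = FALSE], 2, cen)^2
    z2[idx] <- rowSums(dif2[, pos, drop = FALSE]) -
      rowSums(dif2[, !pos, drop = FALSE])
  }
  sqrt(pmax(z2, 0))
}

dispersion_f <- function(z, labels) {
  a <- nlevels(droplevels(labels))
  n <- length(z)
  gm <- tapply(z, labels, mean)
  ng <- table(labels)
  ss_a <- sum(ng * (gm - mean(z))^2)
  ss_w <- sum((z - gm[labels])^2)
  list(f = (ss_a / (a - 1)) / (ss_w / (n - a)),
       r2 = ss_a / (ss_a + ss_w))
}
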