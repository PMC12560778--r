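#' Bray-Curtis dissimilarity
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, bounded in
#' \[0, 1\] for non-negative abundance vectors.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return Dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(1, 0, 3), c(2, 2, 0)) # 0.75
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("vectors differ in length")
  if (any(x < 0) || any(y < 0)) abort("negative abundances")
  tot <- sum(x) + sum(y)
  if (tot == 0) abort("both communities are empty")
  sum(abs(x - y)) / tot
}

#' @rdname bray_curtis
#' @param m a [comm_matrix()]; rows are compared pairwise. Counts are used
#'   as given (convert with [to_relative()] for composition-based
#'   dissimilarity).
#' @export
bray_curtis_matrix <- function(m) {
  x <- cm_counts(m)
  if (any(rowSums(x) == 0)) abort("zero-sum sample in matrix")
  d <- vegan::vegdist(x, method = "bray")
  attr(d, "Labels") <- rownames(x)
  d
}

#' Weighted UniFrac distance
#'
#' Normalised weighted UniFrac between two communities described as
#' proportions over the tips of a rooted tree:
#' \deqn{\sum_b l_b |p_A(b) - p_B(b)| \; / \; \sum_b l_b (p_A(b) + p_B(b))}
#' where \eqn{p(b)} is the fraction of a community descending from branch
#' \eqn{b}. The normalised form is bounded in \[0, 1\].
#'
#' @param x,y abundance vectors named by taxon, or unnamed vectors in
#'   `tree$tip.label` order; internally normalised to proportions.
#' @param tree rooted `phylo` tree whose tips cover the taxa.
#' @return Distance in \[0, 1\].
#' @export
weighted_unifrac <- function(x, y, tree) {
  px <- tip_profile(x, tree)
  py <- tip_profile(y, tree)
  bm <- branch_masses(rbind(px, py), tree)
  num <- sum(tree$edge.length * abs(bm[1, ] - bm[2, ]))
  den <- sum(tree$edge.length * (bm[1, ] + bm[2, ]))
  if (den == 0) abort("both communities are empty")
  num / den
}

tip_profile <- function(x, tree) {
  n_tip <- length(tree$tip.label)
  if (!is.null(names(x))) {
    unknown <- setdiff(names(x)[x > 0], tree$tip.label)
    if (length(unknown))
      abort("taxa not in tree: %s", paste(head(unknown, 5), collapse = ", "))
    v <- setNames(numeric(n_tip), tree$tip.label)
    v[names(x)] <- x
  } else {
    if (length(x) != n_tip) abort("unnamed vector must match tip count")
    v <- setNames(as.numeric(x), tree$tip.label)
  }
  if (sum(v) == 0) abort("empty community")
  v / sum(v)
}

## per-branch descendant proportion mass for each row of a tip-profile
## matrix (columns in tree$tip.label order); returns rows x edges
branch_masses <- function(profiles, tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  acc <- matrix(0, nrow(profiles), n_node)
  acc[, seq_len(n_tip)] <- profiles
  ## accumulate tipward-to-rootward; postorder visits children before parents
  for (e in ape::postorder(tree)) {
    acc[, tree$edge[e, 1]] <- acc[, tree$edge[e, 1]] + acc[, tree$edge[e, 2]]
  }
  acc[, tree$edge[, 2], drop = FALSE]
}

#' @rdname weighted_unifrac
#' @param m a [comm_matrix()] whose taxa are tips of `tree`.
#' @export
weighted_unifrac_matrix <- function(m, tree) {
  x <- cm_counts(m)
  unknown <- setdiff(colnames(x), tree$tip.label)
  if (length(unknown))
    abort("taxa not in tree: %s", paste(head(unknown, 5), collapse = ", "))
  if (any(rowSums(x) == 0)) abort("zero-sum sample in matrix")
  prof <- t(apply(x, 1, function(r) tip_profile(setNames(r, colnames(x)), tree)))
  bm <- branch_masses(prof, tree)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  el <- tree$edge.length
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      num <- sum(el * abs(bm[i, ] - bm[j, ]))
      den <- sum(el * (bm[i, ] + bm[j, ]))
      d[i, j] <- d[j, i] <- num / den
    }
  }
  stats::as.dist(d)
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a dissimilarity matrix: Gower
#' double-centring of \eqn{-d^2/2} followed by eigendecomposition. Axes
#' are ordered by eigenvalue; negative eigenvalues (from non-Euclidean
#' dissimilarities) are reported as-is, and the proportion of variance
#' explained is computed over the positive eigenvalues only.
#'
#' @param d a `dist` object or symmetric matrix of dissimilarities.
#' @param k number of axes to return (default: all positive-eigenvalue axes).
#' @return List with `coordinates` (samples x axes), `eigenvalues`, and
#'   `prop_explained`.
#' @export
pcoa <- function(d, k = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 3) abort("PCoA needs at least 3 samples")
  if (any(abs(dm - t(dm)) > 1e-8)) abort("dissimilarity matrix is not symmetric")
  a <- -0.5 * dm^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  vals <- eig$values
  pos <- vals > max(vals) * 1e-12
  if (is.null(k)) k <- sum(pos)
  k <- min(k, sum(pos))
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k, k)
  rownames(coords) <- rownames(dm) %||% labels(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords,
       eigenvalues = vals,
       prop_explained = ifelse(vals > 0, vals / sum(vals[vals > 0]), 0))
}
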