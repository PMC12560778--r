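#' Community matrix objects
#'
#' A `comm_matrix` holds a samples x taxa abundance table: integer read
#' counts straight from an amplicon pipeline, or per-sample relative
#' abundances after [to_relative()]. It is the central container consumed
#' by every analysis stage of the package.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   unique `rownames` (sample ids) and `colnames` (taxon ids).
#' @param is_relative logical; `TRUE` when rows are proportions summing
#'   to one.
#' @return An object of class `comm_matrix`: the validated matrix with an
#'   `is_relative` attribute.
#' @examples
#' m <- comm_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("s1", "s2"), c("t1", "t2", "t3"))))
#' to_relative(m)
#' @export
comm_matrix <- function(counts, is_relative = FALSE) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) abort("community matrix must be numeric")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("community matrix needs sample rownames and taxon colnames")
  if (anyDuplicated(rownames(counts)))
    abort("duplicate sample ids: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    abort("duplicate taxon ids: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) abort("community matrix contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    abort("negative abundance at sample '%s', taxon '%s'",
          rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  if (is_relative) {
    rs <- rowSums(counts)
    if (any(rs == 0)) abort("relative matrix has zero-sum row '%s'",
                            rownames(counts)[which(rs == 0)[1]])
    if (any(abs(rs - 1) > 1e-9))
      abort("relative rows must sum to 1 (row '%s' sums to %g)",
            rownames(counts)[which.max(abs(rs - 1))], rs[which.max(abs(rs - 1))])
  }
  structure(counts, is_relative = is_relative, class = c("comm_matrix", "matrix", "array"))
}

#' @export
print.comm_matrix <- function(x, ...) {
  cat(sprintf("comm_matrix: %d samples x %d taxa (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "is_relative"))) "relative abundances" else "read counts"))
  cat(sprintf("  depth range: %s\n",
              paste(signif(range(rowSums(x)), 6), collapse = " - ")))
  invisible(x)
}

#' @rdname comm_matrix
#' @param x object to test.
#' @export
is_relative <- function(x) isTRUE(attr(x, "is_relative"))

## strip class for plain matrix maths
cm_counts <- function(m) {
  a <- unclass(m)
  attr(a, "is_relative") <- NULL
  a
}

#' Read and write community matrices
#'
#' `read_community_matrix()` reads a rectangular tab-delimited table with a
#' header row; the first column holds sample ids (or taxon ids when
#' `orientation = "taxa_rows"`, in which case the table is transposed).
#'
#' @param path file path of a TSV table.
#' @param orientation `"samples_rows"` (default) or `"taxa_rows"`.
#' @param is_relative logical, passed to [comm_matrix()].
#' @return A [comm_matrix()].
#' @export
read_community_matrix <- function(path, orientation = c("samples_rows", "taxa_rows"),
                                  is_relative = FALSE) {
  orientation <- match.arg(orientation)
  tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE, comment.char = "")
  mat <- as.matrix(tab)
  if (!is.numeric(mat)) {
    bad <- which(!apply(tab, 2, function(col) all(!is.na(suppressWarnings(as.numeric(col))))))
    abort("non-numeric cells in column(s): %s", paste(names(tab)[bad], collapse = ", "))
  }
  if (orientation == "taxa_rows") mat <- t(mat)
  comm_matrix(mat, is_relative = is_relative)
}

#' @rdname read_community_matrix
#' @param m a [comm_matrix()].
#' @export
write_community_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), cm_counts(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Metadata rows describe one sample each: host species, habitat size
#' (`1-ha`, `10-ha`, `100-ha`, `continuous`) and collection site. The
#' `habitat_class` column (small vs large) is a deterministic recode of
#' habitat size - 1- and 10-ha fragments are "small", 100-ha fragments and
#' continuous forest are "large" - and is recomputed on read.
#'
#' @param path TSV with columns `sample_id`, `host`, `habitat_size`, `site`.
#' @return data.frame with an added/validated `habitat_class` column.
#' @export
read_sample_metadata <- function(path) {
  md <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  need <- c("sample_id", "host", "habitat_size", "site")
  miss <- setdiff(need, names(md))
  if (length(miss)) abort("metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) abort("duplicate sample_id in metadata")
  md$habitat_class <- habitat_class(md$habitat_size)
  md
}

#' @rdname read_sample_metadata
#' @param habitat_size character vector of habitat size labels.
#' @export
habitat_class <- function(habitat_size) {
  cls <- c("1-ha" = "small", "10-ha" = "small",
           "100-ha" = "large", "continuous" = "large")
  unknown <- setdiff(unique(habitat_size), names(cls))
  if (length(unknown))
    abort("unknown habitat_size value(s): %s", paste(unknown, collapse = ", "))
  unname(cls[habitat_size])
}

#' @rdname read_sample_metadata
#' @export
read_taxonomy <- function(path) {
  tx <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  if (!"taxon_id" %in% names(tx)) abort("taxonomy needs a taxon_id column")
  if (anyDuplicated(tx$taxon_id)) abort("duplicate taxon_id in taxonomy")
  tx
}

#' Depth filtering, rarefaction and relative abundance
#'
#' `filter_low_depth()` removes samples whose total read count is below
#' `min_reads` (the conventional guard against shallow libraries).
#' `rarefy()` subsamples every sufficiently deep sample without
#' replacement to a common depth; shallower samples are dropped with a
#' message. `to_relative()` converts counts to per-sample proportions.
#'
#' @param m a [comm_matrix()] of read counts.
#' @param min_reads minimum per-sample read total to retain.
#' @param depth target rarefaction depth (reads per sample).
#' @param seed integer seed making the subsampling reproducible.
#' @return A [comm_matrix()].
#' @export
filter_low_depth <- function(m, min_reads) {
  if (is_relative(m)) abort("filter_low_depth expects read counts, not proportions")
  keep <- rowSums(m) >= min_reads
  if (!any(keep)) abort("all samples fall below %d reads", min_reads)
  comm_matrix(cm_counts(m)[keep, , drop = FALSE])
}

#' @rdname filter_low_depth
#' @export
rarefy <- function(m, depth, seed = NULL) {
  if (is_relative(m)) abort("rarefy expects read counts, not proportions")
  if (depth < 1) abort("rarefaction depth must be >= 1")
  x <- cm_counts(m)
  if (!is_count_matrix(x)) abort("rarefy expects integer read counts")
  keep <- rowSums(x) >= depth
  if (!any(keep)) abort("no sample reaches depth %d", depth)
  if (any(!keep))
    message(sprintf("rarefy: dropping %d sample(s) shallower than %d reads",
                    sum(!keep), depth))
  x <- round(x[keep, , drop = FALSE])
  ## vegan::rrarefy draws the without-replacement (multivariate
  ## hypergeometric) subsample for each row
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(x, depth)))
  stopifnot(all(rowSums(out) == depth))
  comm_matrix(out)
}

#' @rdname filter_low_depth
#' @export
to_relative <- function(m) {
  if (is_relative(m)) return(m)
  rs <- rowSums(m)
  if (any(rs == 0))
    abort("cannot normalise zero-sum sample '%s'", rownames(m)[which(rs == 0)[1]])
  comm_matrix(cm_counts(m) / rs, is_relative = TRUE)
}
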