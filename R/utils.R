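## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## stop() wrapper with sprintf semantics and no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## largest-remainder rounding of a non-negative vector to a fixed integer total
round_to_total <- function(x, total) {
  stopifnot(total >= 0, all(x >= 0))
  if (sum(x) == 0) {
    if (total > 0) abort("cannot allocate %d counts over an all-zero vector", total)
    return(integer(length(x)))
  }
  e <- x / sum(x) * total
  f <- floor(e)
  r <- total - sum(f)
  if (r > 0) {
    o <- order(e - f, decreasing = TRUE)[seq_len(r)]
    f[o] <- f[o] + 1
  }
  as.integer(f)
}

## seeded RNG evaluation that does not clobber the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## derive a stream-specific 31-bit sub-seed from a master seed
## (double arithmetic avoids 32-bit integer overflow)
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 1000003 * as.numeric(stream)) %% 2147483647)
}

is_count_matrix <- function(x) {
  all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}
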