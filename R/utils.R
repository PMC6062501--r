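# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. All generator entry points route their randomness through
# this so that identical config + seed => identical output.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed; stays inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629L + 1)
}

# Reverse cumulative sums down the rows of a matrix: out[k, ] = colSums(m[k:n, ]).
rev_cumsum_rows <- function(m) {
  n <- nrow(m)
  out <- apply(m[n:1, , drop = FALSE], 2, cumsum)
  out <- matrix(out, nrow = n)
  out[n:1, , drop = FALSE]
}

# Reverse cumulative sums along the columns of a matrix (per row):
# out[, k] = rowSums(m[, k:n]).
rev_cumsum_cols <- function(m) {
  n <- ncol(m)
  out <- m[, n:1, drop = FALSE]
  out <- t(apply(out, 1, cumsum))
  out[, n:1, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
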