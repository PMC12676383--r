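# Small shared helpers.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Row-wise softmax with max-subtraction for numerical stability.
softmax_rows <- function(m) {
  m <- as.matrix(m)
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# First-index argmin/argmax over rows of a matrix, skipping non-finite
# entries; rows that are all non-finite return NA.
argmin_rows <- function(D) {
  unname(apply(unname(D), 1, function(r) {
    ok <- is.finite(r)
    if (!any(ok)) return(NA_integer_)
    r[!ok] <- Inf
    as.integer(which.min(r))
  }))
}

argmax_rows <- function(S)
  unname(apply(unname(S), 1, function(r) as.integer(which.max(r))))

# Circular shift of a vector: content moves s positions later.
rotate_vec <- function(x, s) {
  n <- length(x)
  s <- as.integer(s) %% n
  if (s == 0L) return(x)
  x[((seq_len(n) - 1L - s) %% n) + 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
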