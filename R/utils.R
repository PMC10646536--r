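# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb the
# user's stream.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Lexicographic row order of a numeric matrix; used to make seeded k-means
# invariant to the input row order.
canonical_row_order <- function(m) {
  do.call(order, c(lapply(seq_len(ncol(m)), function(j) m[, j]), list(method = "radix")))
}

assert_numeric_matrix <- function(X, what = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("%s must be a numeric matrix or data frame", what), call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop(sprintf("%s contains missing or non-finite values", what), call. = FALSE)
  }
  X
}
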