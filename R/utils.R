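# Internal numerical helpers.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(expm1(z)) without overflow; for large z, expm1(z) ~ exp(z).
log_expm1 <- function(z) {
  ifelse(z > 33, z, log(expm1(z)))
}

# Evaluate expr with a temporarily fixed RNG state, restoring the caller's
# stream afterwards. seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  invisible(x)
}

expm3 <- function(A) {
  as.matrix(Matrix::expm(Matrix::Matrix(A, sparse = FALSE)))
}
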