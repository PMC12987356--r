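# internal numerics shared across modules

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log multivariate beta: log B(a) = sum(lgamma(a)) - lgamma(sum(a))
logBeta <- function(a) sum(lgamma(a)) - lgamma(sum(a))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# expand a scalar or length-n vector to length n, validating positivity
expandPositive <- function(x, n, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stopf("%s must be strictly positive and finite", what)
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n)
    stopf("%s must have length 1 or %d, got %d", what, n, length(x))
  x
}

# expand beta given as scalar / length-V vector / K x V matrix to K x V
expandBetaMatrix <- function(beta, K, V, what = "beta") {
  if (is.matrix(beta)) {
    if (nrow(beta) != K || ncol(beta) != V)
      stopf("%s matrix must be %d x %d", what, K, V)
    if (any(!is.finite(beta)) || any(beta <= 0))
      stopf("%s must be strictly positive and finite", what)
    return(beta)
  }
  row <- expandPositive(beta, V, what)
  matrix(rep(row, each = K), nrow = K, ncol = V)
}
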