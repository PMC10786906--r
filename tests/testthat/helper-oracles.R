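# Independent numerical oracles used to validate the package's spectral and
# algebraic routines. Deliberately naive implementations: they share no code
# with the paths they check.

# Matrix exponential of -gamma * L by scaling-and-squaring of a truncated
# Taylor series (50 terms after scaling the argument below norm 0.5).
expm_oracle <- function(l, gamma = 1, terms = 50L) {
  a <- -gamma * l
  nrm <- max(abs(a)) * nrow(a)
  k <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps) / 0.5)))
  a <- a / 2^k
  acc <- diag(nrow(a))
  term <- diag(nrow(a))
  for (j in seq_len(terms)) {
    term <- term %*% a / j
    acc <- acc + term
  }
  for (j in seq_len(k)) acc <- acc %*% acc
  acc
}

# Three-loop matrix product (no %*%).
matmul_oracle <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(b))) {
      s <- 0
      for (k in seq_len(ncol(a))) s <- s + a[i, k] * b[k, j]
      out[i, j] <- s
    }
  }
  out
}

# Maximum-likelihood (Hill) estimator of a power-law density exponent:
# alpha_hat = 1 + n / sum(log(x / xmin)).
hill_oracle <- function(x, xmin = min(x)) {
  x <- x[x >= xmin]
  1 + length(x) / sum(log(x / xmin))
}

# Characteristic polynomial coefficients of a matrix via the
# Faddeev-LeVerrier recursion; returned in increasing-power order for
# polyroot(): det(xI - A) = c[1] + c[2] x + ... + c[n+1] x^n.
charpoly_coeffs <- function(a) {
  n <- nrow(a)
  c_rev <- numeric(n + 1)   # decreasing powers: x^n ... x^0
  c_rev[1] <- 1
  m <- matrix(0, n, n)
  for (k in seq_len(n)) {
    m <- a %*% m + diag(c_rev[k], n)
    c_rev[k + 1] <- -sum(diag(a %*% m)) / k
  }
  rev(c_rev)
}

# Random connected-ish weighted SC matrix for property tests.
random_sc <- function(n, density = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  w <- runif(sum(up))
  w[runif(sum(up)) > density] <- 0
  a[up] <- w
  a + t(a)
}

# Reference softmax.
softmax_ref <- function(x) exp(x - max(x)) / sum(exp(x - max(x)))

# Direct contingency-table MI in bits (scalar loops, base-2 logs).
mi_oracle <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pxy <- sum(x == a & y == b) / n
      if (pxy > 0) {
        mi <- mi + pxy * log2(pxy / ((sum(x == a) / n) * (sum(y == b) / n)))
      }
    }
  }
  mi
}
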