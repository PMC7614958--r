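# Small numerical helpers shared across modules.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log values.
#' @return log(sum(exp(x))) computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log-density of a multivariate normal
#'
#' @param x numeric vector (or matrix with one row per point).
#' @param mean mean vector.
#' @param cov covariance matrix (symmetric positive definite).
#' @return log-density value(s).
#' @export
dmvnorm_log <- function(x, mean, cov) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  d <- length(mean)
  L <- chol(cov)
  ctr <- sweep(x, 2L, mean)
  z <- backsolve(L, t(ctr), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(L))) - 0.5 * colSums(z^2)
}

#' Draw from a multivariate normal
#'
#' @param n number of draws.
#' @inheritParams dmvnorm_log
#' @return n x d matrix of draws.
#' @export
rmvnorm_chol <- function(n, mean, cov) {
  d <- length(mean)
  L <- chol(cov)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% L, 2L, mean, `+`)
}

#' Log-density of a truncated normal
#'
#' Normal(mu, sd^2) truncated to \[lo, hi\]; returns -Inf outside the bounds.
#' @param x evaluation point(s).
#' @param mu,sd location and scale of the untruncated normal.
#' @param lo,hi truncation bounds.
#' @return log-density value(s).
#' @export
dtnorm_log <- function(x, mu = 0, sd = 2, lo = -10, hi = 10) {
  z <- stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd)
  out <- stats::dnorm(x, mu, sd, log = TRUE) - log(z)
  out[x < lo | x > hi] <- -Inf
  out
}

#' Draw from a truncated normal by inversion
#' @inheritParams dtnorm_log
#' @param n number of draws.
#' @return numeric vector of draws.
#' @export
rtnorm <- function(n, mu = 0, sd = 2, lo = -10, hi = 10) {
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sd)
}

# Derive a stream seed from a root seed; double arithmetic stays exact below
# 2^53, and the result fits a 32-bit integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 1103) %% 2147483399)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
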