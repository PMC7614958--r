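# Independent numerical oracles used across the test files.  These
# deliberately avoid the package's grid utilities: plain Riemann sums on
# fixed lattices, direct density compositions, and hand precision algebra.

# Midpoint-rule integrator over a 2-D lattice for a log-density function
# f(c(x, y)); returns normalising constant, means, covariance, correlation.
riemann2 <- function(logf, lims = c(-8, 8), n = 241) {
  h <- diff(lims) / n
  ax <- seq(lims[1] + h / 2, lims[2] - h / 2, length.out = n)
  g <- expand.grid(x = ax, y = ax)
  lv <- mapply(function(x, y) logf(c(x, y)), g$x, g$y)
  m <- max(lv)
  w <- exp(lv - m)
  Z <- sum(w) * h^2
  p <- w / sum(w)
  mx <- sum(g$x * p); my <- sum(g$y * p)
  vx <- sum((g$x - mx)^2 * p); vy <- sum((g$y - my)^2 * p)
  cxy <- sum((g$x - mx) * (g$y - my) * p)
  list(logZ = m + log(Z), mean = c(mx, my), cov = matrix(c(vx, cxy, cxy, vy), 2),
       cor = cxy / sqrt(vx * vy))
}

riemann1 <- function(logf, lims = c(-8, 8), n = 2001) {
  h <- diff(lims) / n
  ax <- seq(lims[1] + h / 2, lims[2] - h / 2, length.out = n)
  lv <- vapply(ax, function(x) logf(x), 0)
  m <- max(lv)
  list(logZ = m + log(sum(exp(lv - m)) * h), ax = ax, lv = lv)
}

# The two-normal-ends / bivariate-normal-middle pooling setup used in the
# pooling illustrations: mu1 = -2.5, mu3 = 2.5, unit variances, rho = 0.8.
pooling_demo_components <- function(mu1 = -2.5, mu3 = 2.5, rho = 0.8) {
  S2 <- matrix(c(1, rho, rho, 1), 2)
  P2 <- solve(S2)
  l2 <- -log(2 * pi) - 0.5 * log(det(S2))
  list(
    dc1 = density_component(function(x) dnorm(x, mu1, 1, log = TRUE), "phi12"),
    dc2 = density_component(function(x) l2 - 0.5 * drop(x %*% P2 %*% x),
                            c("phi12", "phi23")),
    dc3 = density_component(function(x) dnorm(x, mu3, 1, log = TRUE), "phi23"),
    mu1 = mu1, mu3 = mu3, rho = rho, S2 = S2
  )
}

# Hand precision-addition pooling of the demo components (independent of
# gaussian_pool_closed_form): lambda-weighted precisions embedded and added.
pooling_demo_precision_pool <- function(w, mu1 = -2.5, mu3 = 2.5, rho = 0.8) {
  P <- w[2] * solve(matrix(c(1, rho, rho, 1), 2))
  P[1, 1] <- P[1, 1] + w[1]
  P[2, 2] <- P[2, 2] + w[3]
  b <- c(w[1] * mu1, w[3] * mu3)
  V <- solve(P)
  list(mean = drop(V %*% b), cov = V, cor = V[1, 2] / sqrt(V[1, 1] * V[2, 2]))
}

# Exact subposterior of one end submodel of the Gaussian demo chain:
# theta = (shared, psi), prior N(0, diag(s_shared^2, s_psi^2)),
# y_i ~ N(shared + psi, sd^2).
gaussian_side_exact <- function(y, s_shared = 1.5, s_psi = 1, sd_obs = 1) {
  n <- length(y); tau <- 1 / sd_obs^2
  P <- diag(1 / c(s_shared, s_psi)^2) + tau * n * matrix(1, 2, 2)
  b <- rep(tau * sum(y), 2)
  V <- solve(P)
  list(mean = drop(V %*% b), cov = V)
}

expect_close <- function(x, y, tol) expect_true(all(abs(x - y) < tol))
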