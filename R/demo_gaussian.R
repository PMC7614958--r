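# A fully conjugate Gaussian 3-chain.
#
# Shared quantities: a (submodels 1-2) and b (submodels 2-3), both scalar.
# Each submodel has one idiosyncratic offset psi_m ~ N(0, 1) and observations
#   Y_1: y ~ N(a + psi_1, sd^2),  Y_2: y ~ N(a + b + psi_2, sd^2),
#   Y_3: y ~ N(b + psi_3, sd^2).
# All priors Gaussian and adjacent submodels agree on the shared-quantity
# priors, so with logarithmic pooling weights (1/2, 1/2, 1/2) the melded model
# equals the naturally defined joint model, whose posterior is available in
# closed form by precision bookkeeping.  Used throughout the documentation
# and tests as a transparent benchmark for the two-stage sampler.

#' Simulate data for the Gaussian demonstration chain
#'
#' @param n per-submodel observation counts (length 3).  The default gives
#'   the middle submodel deliberately weaker data than the sides, mirroring
#'   the typical melding situation where the bridging submodel is the least
#'   informative link and the sides contribute most of the information.
#' @param truth list with `a`, `b`, `psi` (length 3).
#' @param sd_obs observation sd.
#' @param seed integer seed.
#' @return list of observation vectors `y1`, `y2`, `y3` plus the inputs.
#' @export
simulate_gaussian_chain <- function(n = c(25, 8, 25),
                                    truth = list(a = 1, b = -0.5,
                                                 psi = c(0.3, -0.2, 0.1)),
                                    sd_obs = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(y1 = stats::rnorm(n[1], truth$a + truth$psi[1], sd_obs),
       y2 = stats::rnorm(n[2], truth$a + truth$b + truth$psi[2], sd_obs),
       y3 = stats::rnorm(n[3], truth$b + truth$psi[3], sd_obs),
       truth = truth, sd_obs = sd_obs)
}

#' Build the Gaussian demonstration chain
#'
#' @param data output of [simulate_gaussian_chain()].
#' @param prior_sd sds of the Gaussian priors: shared `a`, `b` and the
#'   psi offsets (all centred at zero).
#' @param weights logarithmic pooling weights (default (1/2, 1/2, 1/2), under
#'   which the melded model is the joint model).
#' @return list with `chain`, `pooled` (decomposed, subprior sides),
#'   `submodels`.
#' @export
build_gaussian_chain <- function(data, prior_sd = c(a = 1.5, b = 1.5, psi = 1),
                                 weights = c(0.5, 0.5, 0.5)) {
  sd_obs <- data$sd_obs
  sa <- prior_sd[["a"]]; sb <- prior_sd[["b"]]; sp <- prior_sd[["psi"]]
  sub1 <- submodel_spec(
    "left-gaussian",
    log_joint = function(phi, psi)
      stats::dnorm(phi[["a"]], 0, sa, log = TRUE) +
      stats::dnorm(psi, 0, sp, log = TRUE) +
      sum(stats::dnorm(data$y1, phi[["a"]] + psi, sd_obs, log = TRUE)),
    log_phi_marginal = function(phi) stats::dnorm(phi[["a"]], 0, sa, log = TRUE),
    phi_right = "a", psi_names = "psi1", psi_init = 0, phi_init = c(a = 0))
  sub2 <- submodel_spec(
    "middle-gaussian",
    log_joint = function(phi, psi)
      stats::dnorm(phi[["a"]], 0, sa, log = TRUE) +
      stats::dnorm(phi[["b"]], 0, sb, log = TRUE) +
      stats::dnorm(psi, 0, sp, log = TRUE) +
      sum(stats::dnorm(data$y2, phi[["a"]] + phi[["b"]] + psi, sd_obs, log = TRUE)),
    log_phi_marginal = function(phi)
      stats::dnorm(phi[["a"]], 0, sa, log = TRUE) +
      stats::dnorm(phi[["b"]], 0, sb, log = TRUE),
    phi_left = "a", phi_right = "b", psi_names = "psi2", psi_init = 0)
  sub3 <- submodel_spec(
    "right-gaussian",
    log_joint = function(phi, psi)
      stats::dnorm(phi[["b"]], 0, sb, log = TRUE) +
      stats::dnorm(psi, 0, sp, log = TRUE) +
      sum(stats::dnorm(data$y3, phi[["b"]] + psi, sd_obs, log = TRUE)),
    log_phi_marginal = function(phi) stats::dnorm(phi[["b"]], 0, sb, log = TRUE),
    phi_left = "b", psi_names = "psi3", psi_init = 0, phi_init = c(b = 0))
  chain <- chain_model(list(sub1, sub2, sub3))
  dc1 <- density_component(function(x) stats::dnorm(x, 0, sa, log = TRUE), "a")
  dc2 <- density_component(function(x)
    stats::dnorm(x[1], 0, sa, log = TRUE) + stats::dnorm(x[2], 0, sb, log = TRUE),
    c("a", "b"))
  dc3 <- density_component(function(x) stats::dnorm(x, 0, sb, log = TRUE), "b")
  pooled <- pool_log(list(dc1, dc2, dc3), weights)
  pooled <- decompose_pooled(pooled, "subprior-sides", side_priors = list(dc1, dc3))
  list(chain = chain, pooled = pooled, submodels = list(sub1, sub2, sub3),
       prior_sd = prior_sd)
}

#' Exact posterior of the Gaussian joint model by precision bookkeeping
#'
#' The joint model over theta = (a, b, psi1, psi2, psi3) is Gaussian; its
#' posterior precision is the prior precision plus `X'X / sd_obs^2` summed
#' over the three observation blocks, with matching shift.  This closed form
#' equals the melded posterior under logarithmic pooling with weights
#' (1/2, 1/2, 1/2) when adjacent submodels share their shared-quantity
#' priors.
#'
#' @param data output of [simulate_gaussian_chain()].
#' @param prior_sd as in [build_gaussian_chain()].
#' @return a [gaussian_summary()] over (a, b, psi1, psi2, psi3).
#' @export
gaussian_chain_exact_posterior <- function(data,
                                           prior_sd = c(a = 1.5, b = 1.5, psi = 1)) {
  vars <- c("a", "b", "psi1", "psi2", "psi3")
  P <- diag(1 / c(prior_sd[["a"]], prior_sd[["b"]], rep(prior_sd[["psi"]], 3))^2)
  b <- numeric(5)
  tau <- 1 / data$sd_obs^2
  blocks <- list(list(idx = c(1, 3), y = data$y1),
                 list(idx = c(1, 2, 4), y = data$y2),
                 list(idx = c(2, 5), y = data$y3))
  for (bl in blocks) {
    n <- length(bl$y); s <- sum(bl$y)
    P[bl$idx, bl$idx] <- P[bl$idx, bl$idx] + tau * n
    b[bl$idx] <- b[bl$idx] + tau * s
  }
  cov <- solve(P)
  gaussian_summary(drop(cov %*% b), (cov + t(cov)) / 2, vars = vars)
}
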