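# A fully discrete 3-chain on {0,1,2}^3 whose melded posterior can be
# enumerated exactly.  Shared quantities i = phi_{1^2} and j = phi_{2^3};
# the middle submodel has one idiosyncratic variable k = psi_2.  All prior
# and likelihood tables are strictly positive, so every Metropolis ratio is
# finite and the three stage-two block kernels can be written down as
# matrices.  Used in the documentation and tests to check the sampler against
# brute-force enumeration.

#' Build the discrete demonstration chain
#'
#' Tables are deterministic functions of `seed` (drawn once, then fixed), so
#' the same seed always defines the same chain.
#'
#' @param seed integer seed for the table draws.
#' @param weights logarithmic pooling weights.
#' @return list with `submodels`, `chain`, `pooled` (decomposed, subprior
#'   sides), the `tables`, and `states` (the 3 support points `0:2`).
#' @export
discrete_chain_demo <- function(seed = 1, weights = c(1, 1, 1)) {
  set.seed(derive_seed(seed, 91))
  states <- 0:2
  q1 <- stats::runif(3, 0.2, 1); q1 <- q1 / sum(q1)           # p_1(i)
  q2 <- matrix(stats::runif(9, 0.2, 1), 3, 3); q2 <- q2 / sum(q2)  # p_2(i, j)
  q3 <- stats::runif(3, 0.2, 1); q3 <- q3 / sum(q3)           # p_3(j)
  r2 <- stats::runif(3, 0.2, 1); r2 <- r2 / sum(r2)           # p_2(k)
  L1 <- stats::runif(3, 0.2, 2)                               # p(Y_1 | i)
  L2 <- array(stats::runif(27, 0.2, 2), c(3, 3, 3))           # p(Y_2 | i, j, k)
  L3 <- stats::runif(3, 0.2, 2)                               # p(Y_3 | j)
  tables <- list(q1 = q1, q2 = q2, q3 = q3, r2 = r2, L1 = L1, L2 = L2, L3 = L3)
  sup1 <- list(discrete_set(states))
  sub1 <- submodel_spec(
    "left-discrete",
    log_joint = function(phi, psi) log(q1[phi[["i"]] + 1]) + log(L1[phi[["i"]] + 1]),
    log_phi_marginal = function(phi) log(q1[phi[["i"]] + 1]),
    phi_right = "i", phi_init = c(i = 0),
    sampler = local({
      p <- q1 * L1 / sum(q1 * L1)
      function(n, seed = NULL) {
        if (!is.null(seed)) set.seed(seed)
        matrix(sample(states, n, replace = TRUE, prob = p), ncol = 1)
      }
    }))
  sub2 <- submodel_spec(
    "middle-discrete",
    log_joint = function(phi, psi)
      log(q2[phi[["i"]] + 1, phi[["j"]] + 1]) + log(r2[psi + 1]) +
      log(L2[phi[["i"]] + 1, phi[["j"]] + 1, psi + 1]),
    log_phi_marginal = function(phi) log(q2[phi[["i"]] + 1, phi[["j"]] + 1]),
    phi_left = "i", phi_right = "j", psi_names = "k", psi_init = 0)
  sub3 <- submodel_spec(
    "right-discrete",
    log_joint = function(phi, psi) log(q3[phi[["j"]] + 1]) + log(L3[phi[["j"]] + 1]),
    log_phi_marginal = function(phi) log(q3[phi[["j"]] + 1]),
    phi_left = "j", phi_init = c(j = 0),
    sampler = local({
      p <- q3 * L3 / sum(q3 * L3)
      function(n, seed = NULL) {
        if (!is.null(seed)) set.seed(seed)
        matrix(sample(states, n, replace = TRUE, prob = p), ncol = 1)
      }
    }))
  chain <- chain_model(list(sub1, sub2, sub3))
  dc1 <- density_component(function(x) log(q1[x + 1]), "i", support = sup1)
  dc2 <- density_component(function(x) log(q2[x[1] + 1, x[2] + 1]), c("i", "j"),
                           support = list(discrete_set(states), discrete_set(states)))
  dc3 <- density_component(function(x) log(q3[x + 1]), "j",
                           support = list(discrete_set(states)))
  pooled <- pool_log(list(dc1, dc2, dc3), weights)
  pooled <- decompose_pooled(pooled, "subprior-sides", side_priors = list(dc1, dc3))
  list(submodels = list(sub1, sub2, sub3), chain = chain, pooled = pooled,
       tables = tables, states = states)
}

#' Enumerate the melded posterior of the discrete chain
#'
#' Evaluates the melded log-density at each of the 27 states `(i, j, k)` and
#' normalises.
#'
#' @param demo output of [discrete_chain_demo()].
#' @return 3 x 3 x 3 probability array over (i, j, k).
#' @export
discrete_melded_posterior <- function(demo) {
  model <- melded_model(demo$chain, demo$pooled)
  p <- array(NA_real_, c(3, 3, 3))
  for (i in 0:2) for (j in 0:2) for (k in 0:2) {
    p[i + 1, j + 1, k + 1] <- melded_log_density(
      model, c(i = i, j = j), list(numeric(0), k, numeric(0)))
  }
  p <- exp(p - max(p))
  p / sum(p)
}

#' Uniform-proposal psi_2 kernel for a discrete variable
#'
#' Proposes a state uniformly from `states` (independent, symmetric) and
#' accepts by the middle-submodel ratio.
#'
#' @param states vector of allowed values.
#' @return kernel function for [run_stage_two()]'s `psi2_kernel` argument.
#' @export
discrete_psi2_kernel <- function(states = 0:2) {
  function(psi2, phi, middle, sweep) {
    prop <- sample(states, 1)
    a <- accept_prob_psi2(prop, psi2, middle, phi)
    acc <- stats::runif(1) < a
    list(psi2 = if (acc) prop else psi2, accepted = as.integer(acc), attempts = 1L)
  }
}
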