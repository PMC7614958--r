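# Integrated population model for little owls: three submodels joined in a
# chain.  Capture-recapture data (multinomial recapture-time likelihood)
# inform survival; census counts of females inform a latent
# Poisson/binomial population process; nest-record data inform fecundity.
# Shared quantities: phi_{1^2} = (alpha0, alpha2) (survival intercept and
# adult effect, logit scale) and phi_{2^3} = rho (fledglings per breeding
# female per year).

ipm_ages <- c("J", "A")
ipm_sexes <- c("F", "M")
ipm_strata <- as.vector(outer(ipm_ages, ipm_sexes, paste, sep = "_"))

#' Linear-predictor link for the IPM rates
#'
#' `logit(delta_{a,s,t}) = alpha0 + alpha1 I(s = M) + alpha2 I(a = A)` (so
#' survival is constant over time), `logit(pi_{s,u}) = alpha4 I(s = M) +
#' alpha5_u` for recapture years `u = 2..T`, and `log(eta_t) = alpha6`.
#'
#' @param coef list with scalars `alpha0`, `alpha1`, `alpha2`, `alpha4`,
#'   `alpha6` and vector `alpha5` of length T-1 (years 2..T).
#' @param T number of study years.
#' @return list: `delta` array `[age, sex, t]`, `pi` matrix `[sex, u]`
#'   (column 1 is `NA`; recapture starts the year after release), `eta`
#'   length-T vector.
#' @export
link_rates <- function(coef, T) {
  stopifnot(length(coef$alpha5) == T - 1)
  delta <- array(NA_real_, c(2, 2, T), dimnames = list(ipm_ages, ipm_sexes, NULL))
  for (a in ipm_ages) for (s in ipm_sexes) {
    delta[a, s, ] <- stats::plogis(coef$alpha0 + coef$alpha1 * (s == "M") +
                                     coef$alpha2 * (a == "A"))
  }
  pi <- matrix(NA_real_, 2, T, dimnames = list(ipm_sexes, NULL))
  for (s in ipm_sexes) {
    pi[s, 2:T] <- stats::plogis(coef$alpha4 * (s == "M") + coef$alpha5)
  }
  eta <- rep(exp(coef$alpha6), T)
  list(delta = delta, pi = pi, eta = eta)
}

#' Recapture-time cell probabilities for one stratum
#'
#' Releases at year t are first recaptured at year u with probability
#' `delta_t pi_u prod_{r=t+1}^{u-1} delta_r (1 - pi_r)`; the final column
#' (u = T + 1, never recaptured) is the complement so each row sums to 1.
#'
#' @param delta length-T survival probabilities for this age/sex stratum.
#' @param pi length-T recapture probabilities (element 1 unused).
#' @param T number of study years.
#' @return T x (T + 1) matrix of row-simplex probabilities.
#' @export
recapture_cell_probs <- function(delta, pi, T) {
  Q <- matrix(0, T, T + 1)
  g <- delta[2:T] * (1 - pi[2:T])   # survive year r, not recaptured (r = 2..T)
  if (all(g > 0)) {
    # S(t, u) = prod_{r=t+1}^{u-1} g_r via cumulative logs, whole triangle at once
    cl <- c(0, cumsum(log(g)))      # cl[i] = sum over r = 2..i
    tt <- matrix(seq_len(T), T, T)
    uu <- t(tt)
    up <- uu > tt
    Q[, seq_len(T)][up] <- delta[tt[up]] * pi[uu[up]] * exp(cl[uu[up] - 1] - cl[tt[up]])
  } else {
    for (t in seq_len(T - 1)) {
      us <- (t + 1):T
      gr <- delta[us] * (1 - pi[us])
      cp <- cumprod(c(1, gr[-length(gr)])) # prod over r = t+1 .. u-1
      Q[t, us] <- delta[t] * pi[us] * cp
    }
  }
  Q[, T + 1] <- 1 - rowSums(Q[, seq_len(T), drop = FALSE])
  Q
}

#' Multinomial capture-recapture log-likelihood
#'
#' @param cr capture-recapture data: list with `M` (named list of
#'   T x (T+1) count matrices, one per `J_F`, `J_M`, `A_F`, `A_M` stratum) and
#'   `R` (named list of length-T release totals, the row sums of `M`).
#' @param Q named list of probability matrices from
#'   [recapture_cell_probs()], same strata.
#' @return scalar log-likelihood; `-Inf` when a positive count sits on a
#'   zero-probability cell.
#' @export
cr_loglik <- function(cr, Q) {
  tot <- 0
  for (st in names(cr$M)) {
    m <- cr$M[[st]]; q <- Q[[st]]
    lq <- ifelse(m > 0, log(q), 0)
    if (any(m > 0 & q == 0)) return(-Inf)
    tot <- tot + sum(lgamma(cr$R[[st]] + 1)) - sum(lgamma(m + 1)) + sum(m * lq)
  }
  tot
}

is_count <- function(x) all(is.finite(x)) && all(x >= 0) && all(x == round(x))

#' Count-data (state-space) log-likelihood
#'
#' Observation level: `y_t ~ Poisson(x_t)` with `x_t = x_{J,t} + x_{A,t}`.
#' Latent level, for t = 2..T:
#' `x_{J,t} ~ Poisson(x_{t-1} (rho/2) delta_{J,F,t-1})` (half of fledglings
#' are female), `sur_t ~ Binomial(x_{t-1}, delta_{A,F,t-1})`,
#' `imm_t ~ Poisson(x_{t-1} eta_t)`, `x_{A,t} = sur_t + imm_t`.  A zero
#' population at t-1 turns all three into point masses at zero.
#'
#' @param y length-T observed female counts.
#' @param xJ length-T juvenile female counts (latent).
#' @param xA1 initial adult female count (latent).
#' @param sur,imm length-T survivor/immigrant counts (element 1 unused).
#' @param rho fecundity.
#' @param delta_JF,delta_AF length-T juvenile/adult female survival.
#' @param eta length-T immigration rate.
#' @return scalar log-density of (y, latents); `-Inf` for invalid latents
#'   (negative, non-integer, or `sur_t > x_{t-1}`).
#' @export
count_loglik <- function(y, xJ, xA1, sur, imm, rho, delta_JF, delta_AF, eta) {
  T <- length(y)
  if (!is_count(xJ) || !is_count(xA1) || !is_count(sur[-1]) || !is_count(imm[-1]))
    return(-Inf)
  if (!is.finite(rho) || rho < 0) return(-Inf)
  xA <- c(xA1, sur[2:T] + imm[2:T])
  x <- xJ + xA
  ll <- sum(stats::dpois(y, x, log = TRUE))
  if (ll == -Inf) return(-Inf)
  xprev <- x[1:(T - 1)]
  ll <- ll +
    sum(stats::dpois(xJ[2:T], xprev * (rho / 2) * delta_JF[1:(T - 1)], log = TRUE)) +
    sum(stats::dbinom(sur[2:T], xprev, delta_AF[1:(T - 1)], log = TRUE)) +
    sum(stats::dpois(imm[2:T], xprev * eta[2:T], log = TRUE))
  if (is.nan(ll)) -Inf else ll
}

#' Fecundity log-likelihood
#'
#' `n_t ~ Poisson(N_t rho)`: fledged chicks given breeding females.
#'
#' @param N length-T breeding-female counts.
#' @param n length-T fledgling counts.
#' @param rho fecundity (expected fledglings per breeding female).
#' @return scalar log-likelihood.
#' @export
fecundity_loglik <- function(N, n, rho) {
  if (!is.finite(rho) || rho < 0) return(-Inf)
  sum(stats::dpois(n, N * rho, log = TRUE))
}

# Truncated-normal prior shared by all regression coefficients.
ipm_alpha_lprior <- function(x) sum(dtnorm_log(x, 0, 2, -10, 10))

ipm_rho_lprior <- function(rho) stats::dunif(rho, 0, 10, log = TRUE)

ipm_init_pop_lprior <- function(x) {
  if (x %in% 0:50) -log(51) else -Inf
}

#' Joint prior log-density of the IPM parameters
#'
#' Truncated Normal(0, 2^2) on \[-10, 10\] for every regression coefficient
#' (alpha0, alpha1, alpha2, alpha4, alpha6 and each alpha5_u), Uniform(0, 10)
#' for rho, and independent discrete uniforms on {0, ..., 50} for the initial
#' populations.
#'
#' @param coef coefficient list as in [link_rates()].
#' @param rho fecundity.
#' @param xJ1,xA1 initial juvenile/adult female counts.
#' @return scalar log prior density.
#' @export
ipm_log_priors <- function(coef, rho, xJ1, xA1) {
  ipm_alpha_lprior(c(coef$alpha0, coef$alpha1, coef$alpha2, coef$alpha4,
                     coef$alpha6, coef$alpha5)) +
    ipm_rho_lprior(rho) + ipm_init_pop_lprior(xJ1) + ipm_init_pop_lprior(xA1)
}

#' Default generating parameters for the simulator
#'
#' Realistic little-owl values: juvenile female survival ~0.30, adult ~0.50,
#' males slightly lower; recapture probability ~0.62 (females); immigration
#' rate 0.20/year; fecundity 2.6 fledglings per breeding female.
#'
#' @param T number of study years.
#' @return list of generating parameters.
#' @export
ipm_true_state <- function(T = 15) {
  list(alpha0 = stats::qlogis(0.30),            # ~ -0.847
       alpha1 = -0.30,
       alpha2 = stats::qlogis(0.50) - stats::qlogis(0.30),  # ~ 0.847
       alpha4 = -0.20,
       alpha5 = rep(0.50, T - 1),
       alpha6 = log(0.20),
       rho = 2.6, xJ1 = 15, xA1 = 20)
}

#' Simulate capture-recapture, count, and fecundity data
#'
#' Draws from the exact model likelihoods: the latent population process and
#' census counts, multinomial recapture times for a fixed number of releases
#' per stratum-year, and Poisson fledgling counts.  Breeding females `N_t`
#' are set to the realised female population `x_t`.
#'
#' @param truth generating parameters, see [ipm_true_state()].
#' @param T number of years (>= 3).
#' @param releases releases per stratum and year (scalar).
#' @param seed integer seed.
#' @return list with `cr`, `counts` (`y`), `fec` (`N`, `n`), the generating
#'   `truth` and realised `latents`.
#' @export
simulate_ipm <- function(truth = ipm_true_state(T), T = 15, releases = 50,
                         seed = NULL) {
  stopifnot(T >= 3)
  if (!is.null(seed)) set.seed(seed)
  rates <- link_rates(truth, T)
  dJF <- rates$delta["J", "F", ]; dAF <- rates$delta["A", "F", ]
  xJ <- sur <- imm <- integer(T)
  xJ[1] <- truth$xJ1
  xA <- integer(T); xA[1] <- truth$xA1
  for (t in 2:T) {
    xprev <- xJ[t - 1] + xA[t - 1]
    xJ[t] <- stats::rpois(1, xprev * (truth$rho / 2) * dJF[t - 1])
    sur[t] <- stats::rbinom(1, xprev, dAF[t - 1])
    imm[t] <- stats::rpois(1, xprev * rates$eta[t])
    xA[t] <- sur[t] + imm[t]
  }
  x <- xJ + xA
  y <- stats::rpois(T, x)
  M <- list(); R <- list()
  for (a in ipm_ages) for (s in ipm_sexes) {
    st <- paste(a, s, sep = "_")
    Q <- recapture_cell_probs(rates$delta[a, s, ], rates$pi[s, ], T)
    Mst <- matrix(0L, T, T + 1)
    for (t in seq_len(T)) Mst[t, ] <- as.integer(stats::rmultinom(1, releases, Q[t, ]))
    M[[st]] <- Mst
    R[[st]] <- rowSums(Mst)
  }
  n <- stats::rpois(T, x * truth$rho)
  list(cr = list(M = M, R = R),
       counts = list(y = y),
       fec = list(N = x, n = n),
       truth = truth,
       latents = list(xJ = xJ, xA = xA, sur = sur, imm = imm, x = x))
}

# ---- submodel assembly -------------------------------------------------------

# psi_2 layout: (alpha6, xJ[1..T], xA1, sur[2..T], imm[2..T])
ipm_psi2_names <- function(T) {
  c("alpha6", paste0("xJ[", 1:T, "]"), "xA1",
    paste0("sur[", 2:T, "]"), paste0("imm[", 2:T, "]"))
}

ipm_unpack_psi2 <- function(psi, T) {
  list(alpha6 = psi[1],
       xJ = psi[2:(T + 1)],
       xA1 = psi[T + 2],
       sur = c(NA_real_, psi[(T + 3):(2 * T + 1)]),
       imm = c(NA_real_, psi[(2 * T + 2):(3 * T)]))
}

ipm_pack_psi2 <- function(alpha6, xJ, xA1, sur, imm) {
  c(alpha6, xJ, xA1, sur[-1], imm[-1])
}

ipm_submodel_cr <- function(cr, T) {
  # precomputed structure: upper-triangle indices, sparse positive-count cells
  # and the data-constant multinomial coefficients
  tt <- matrix(seq_len(T), T, T); uu <- t(tt)
  up <- which(uu > tt)
  t_of <- tt[up]; u_of <- uu[up]; du <- u_of - t_of
  lin <- t_of + (u_of - 1L) * T          # linear index into a T x (T+1) matrix
  sparse <- lapply(cr$M, function(m) {
    idx <- which(m > 0)
    list(idx = idx, mval = m[idx],
         const = sum(lgamma(rowSums(m) + 1)) - sum(lgamma(m + 1)))
  })
  # survival is constant in time within a stratum (linear-predictor link), so
  # each stratum needs one delta scalar and the sex-specific recapture vector
  stratum_ll <- function(delta, pi, sp) {
    c1 <- c(0, cumsum(log1p(-pi[2:T])))  # c1[i] = sum_{r=2..i} log(1 - pi_r)
    cells <- exp(log(delta) * du + log(pi[u_of]) + c1[u_of - 1] - c1[t_of])
    Qm <- matrix(0, T, T + 1)
    Qm[lin] <- cells
    Qm[, T + 1] <- 1 - rowSums(Qm[, seq_len(T), drop = FALSE])
    q <- Qm[sp$idx]
    if (any(q <= 0)) return(-Inf)
    sp$const + sum(sp$mval * log(q))
  }
  log_joint <- function(phi, psi) {
    a0 <- phi[["alpha0"]]; a2 <- phi[["alpha2"]]
    a1 <- psi[1]; a4 <- psi[2]; a5 <- psi[3:(T + 1)]
    lpri <- ipm_alpha_lprior(c(a0, a2, a1, a4, a5))
    if (lpri == -Inf) return(-Inf)
    piF <- c(NA, stats::plogis(a5))
    piM <- c(NA, stats::plogis(a4 + a5))
    ll <- stratum_ll(stats::plogis(a0), piF, sparse$J_F) +
      stratum_ll(stats::plogis(a0 + a1), piM, sparse$J_M) +
      stratum_ll(stats::plogis(a0 + a2), piF, sparse$A_F) +
      stratum_ll(stats::plogis(a0 + a1 + a2), piM, sparse$A_M)
    lpri + ll
  }
  submodel_spec(
    name = "capture-recapture",
    log_joint = log_joint,
    log_phi_marginal = function(phi) ipm_alpha_lprior(c(phi[["alpha0"]], phi[["alpha2"]])),
    phi_right = c("alpha0", "alpha2"),
    psi_names = c("alpha1", "alpha4", paste0("alpha5[", 2:T, "]")),
    psi_init = rep(0, T + 1), phi_init = c(alpha0 = 0, alpha2 = 0))
}

ipm_submodel_count <- function(y, T) {
  log_joint <- function(phi, psi) {
    a0 <- phi[["alpha0"]]; a2 <- phi[["alpha2"]]; rho <- phi[["rho"]]
    lpri <- ipm_alpha_lprior(c(a0, a2)) + ipm_rho_lprior(rho)
    if (lpri == -Inf) return(-Inf)
    p <- ipm_unpack_psi2(psi, T)
    lpri <- lpri + ipm_alpha_lprior(p$alpha6) +
      ipm_init_pop_lprior(p$xJ[1]) + ipm_init_pop_lprior(p$xA1)
    if (lpri == -Inf) return(-Inf)
    dJF <- rep(stats::plogis(a0), T)
    dAF <- rep(stats::plogis(a0 + a2), T)
    eta <- rep(exp(p$alpha6), T)
    lpri + count_loglik(y, p$xJ, p$xA1, p$sur, p$imm, rho, dJF, dAF, eta)
  }
  submodel_spec(
    name = "counts",
    log_joint = log_joint,
    log_phi_marginal = function(phi)
      ipm_alpha_lprior(c(phi[["alpha0"]], phi[["alpha2"]])) + ipm_rho_lprior(phi[["rho"]]),
    phi_left = c("alpha0", "alpha2"), phi_right = "rho",
    psi_names = ipm_psi2_names(T))
}

ipm_submodel_fec <- function(N, n, T) {
  shape <- sum(n) + 1; rate <- sum(N)
  sampler <- function(m, seed = NULL) {
    # exact subposterior under the Uniform(0,10) prior: Gamma truncated to (0,10)
    if (!is.null(seed)) set.seed(seed)
    plo <- stats::pgamma(0, shape, rate); phi <- stats::pgamma(10, shape, rate)
    matrix(stats::qgamma(plo + stats::runif(m) * (phi - plo), shape, rate), ncol = 1)
  }
  submodel_spec(
    name = "fecundity",
    log_joint = function(phi, psi) {
      rho <- phi[["rho"]]
      lp <- ipm_rho_lprior(rho)
      if (lp == -Inf) return(-Inf)
      lp + fecundity_loglik(N, n, rho)
    },
    log_phi_marginal = function(phi) ipm_rho_lprior(phi[["rho"]]),
    phi_left = "rho", sampler = sampler, phi_init = c(rho = 1))
}

ipm_phi_marginal_dcs <- function() {
  tn2 <- function(x) sum(dtnorm_log(x, 0, 2, -10, 10))
  list(
    p1 = density_component(tn2, vars = c("alpha0", "alpha2"),
                           support = list(c(-10, 10), c(-10, 10))),
    p2 = density_component(function(x) tn2(x[1:2]) + stats::dunif(x[3], 0, 10, log = TRUE),
                           vars = c("alpha0", "alpha2", "rho"),
                           support = list(c(-10, 10), c(-10, 10), c(0, 10))),
    p3 = density_component(function(x) stats::dunif(x, 0, 10, log = TRUE),
                           vars = "rho", support = list(c(0, 10)))
  )
}

#' Assemble the IPM chain and pooled prior
#'
#' Wires the three submodels with shared slots `(alpha0, alpha2)` and `rho`
#' and builds the pooled prior under the requested operator.  Because the
#' submodels place identical independent priors on the shared quantities,
#' logarithmic pooling with weights (1/2, 1/2, 1/2) — and linear pooling with
#' equal weights — reproduce those priors exactly, making the melded model
#' identical to the monolithic joint IPM; product-of-experts pooling squares
#' the truncated-normal prior for (alpha0, alpha2).
#'
#' @param data simulated or observed data triple, as from [simulate_ipm()].
#' @param pooling one of "logarithmic", "poe", "linear".
#' @return list with `chain` ([chain_model()]), `pooled` (decomposed with
#'   subprior sides, so stage one targets the ordinary subposteriors),
#'   `submodels`, and `T`.
#' @export
build_ipm_chain <- function(data, pooling = c("logarithmic", "poe", "linear")) {
  pooling <- match.arg(pooling)
  T <- length(data$counts$y)
  subs <- list(ipm_submodel_cr(data$cr, T),
               ipm_submodel_count(data$counts$y, T),
               ipm_submodel_fec(data$fec$N, data$fec$n, T))
  chain <- chain_model(subs)
  dcs <- ipm_phi_marginal_dcs()
  pooled <- switch(
    pooling,
    logarithmic = pool_log(dcs, weights = c(0.5, 0.5, 0.5)),
    poe = pool_log(dcs, weights = c(1, 1, 1)),
    linear = {
      p2_left <- density_component(
        function(x) sum(dtnorm_log(x, 0, 2, -10, 10)),
        vars = c("alpha0", "alpha2"),
        support = list(c(-10, 10), c(-10, 10)))
      p2_right <- density_component(
        function(x) stats::dunif(x, 0, 10, log = TRUE),
        vars = "rho", support = list(c(0, 10)))
      pool_linear(list(list(dcs$p1, p2_left), list(p2_right, dcs$p3)),
                  weights = list(c(0.5, 0.5), c(0.5, 0.5)))
    })
  pooled <- decompose_pooled(pooled, "subprior-sides",
                             side_priors = list(dcs$p1, dcs$p3))
  list(chain = chain, pooled = pooled, submodels = subs, T = T)
}

# ---- samplers for the IPM ----------------------------------------------------

# Latent-state initialisation consistent with the observed counts.
ipm_psi2_start <- function(y, T) {
  x0 <- pmax(1, y)
  xJ <- pmax(0, round(x0 * 0.4))
  xA <- x0 - xJ
  sur <- c(NA, pmin(round(x0[1:(T - 1)] * 0.5), x0[1:(T - 1)]))
  imm <- c(NA, pmax(0, xA[2:T] - sur[2:T]))
  sur <- c(NA, xA[2:T] - imm[2:T])
  ipm_pack_psi2(log(0.2), xJ, min(xA[1], 50), sur, imm)
}

#' Single-site psi_2 kernel for the IPM count submodel
#'
#' One call sweeps: a Gaussian random-walk move on alpha6, then discrete
#' random-walk (+/-1, +/-2) moves on each latent count (initial populations,
#' juveniles, survivors, immigrants).  Valid for
#' `p_2(phi, psi_2, Y_2)` at fixed phi; used as the stage-two psi_2 block and
#' inside the count-only and joint samplers.
#'
#' @param T number of years.
#' @param alpha6_scale random-walk sd for alpha6.
#' @return kernel function for [run_stage_two()]'s `psi2_kernel` argument.
#' @export
ipm_psi2_kernel <- function(T, alpha6_scale = 0.3) {
  d <- 3 * T
  steps <- c(-2L, -1L, 1L, 2L)
  function(psi2, phi, middle, sweep) {
    lcur <- middle$log_joint(phi, psi2)
    accepted <- 0L
    # alpha6
    prop <- psi2
    prop[1] <- prop[1] + stats::rnorm(1, 0, alpha6_scale)
    lp <- middle$log_joint(phi, prop)
    if (lp - lcur > log(stats::runif(1))) { psi2 <- prop; lcur <- lp; accepted <- accepted + 1L }
    # latent counts
    for (j in 2:d) {
      prop <- psi2
      prop[j] <- prop[j] + sample(steps, 1)
      if (prop[j] >= 0) {
        lp <- middle$log_joint(phi, prop)
        if (lp - lcur > log(stats::runif(1))) { psi2 <- prop; lcur <- lp; accepted <- accepted + 1L }
      }
    }
    list(psi2 = psi2, accepted = accepted, attempts = d)
  }
}

#' Fit the IPM by two-stage melding
#'
#' Stage one: adaptive random-walk MCMC on the capture-recapture subposterior
#' and exact draws from the fecundity subposterior.  Stage two:
#' Metropolis-within-Gibbs on the melded posterior with stage-one draws
#' recycled as side proposals and the single-site kernel for the count
#' submodel's latent states.
#'
#' @param data data triple from [simulate_ipm()].
#' @param pooling pooling operator, see [build_ipm_chain()].
#' @param n_stage1 stage-one draws per side.
#' @param sweeps,chains stage-two retained sweeps and number of chains.
#' @param seed root seed; all stage streams derive from it.
#' @param stage1_warmup,stage1_thin stage-one MCMC settings for the
#'   capture-recapture side.
#' @return list with `chains` (a `melded_chains`), `draws` (stacked matrix),
#'   `side1`, `side3`, and the built `model`.
#' @export
fit_ipm_meld <- function(data, pooling = "logarithmic", n_stage1 = 2000,
                         sweeps = 3000, chains = 2, seed = 1,
                         stage1_warmup = 4000, stage1_thin = 4) {
  model <- build_ipm_chain(data, pooling)
  T <- model$T
  side1 <- sample_stage_one(model$submodels[[1]], model$pooled$factors$left,
                            n_keep = n_stage1, warmup = stage1_warmup,
                            thin = stage1_thin, scale = 0.05,
                            seed = derive_seed(seed, 1))
  side3 <- sample_stage_one(model$submodels[[3]], model$pooled$factors$right,
                            n_keep = n_stage1, seed = derive_seed(seed, 3))
  ch <- run_stage_two_chains(side1, side3, model$submodels[[2]], model$pooled,
                             chains = chains, seed = seed, sweeps = sweeps,
                             psi2_init = ipm_psi2_start(data$counts$y, T),
                             psi2_kernel = ipm_psi2_kernel(T))
  list(chains = ch, draws = combine_chains(ch), side1 = side1, side3 = side3,
       model = model)
}

# Generic single-site sampler over (phi, psi2) used by the count-only and
# joint-model fits: scalar adaptive RW on the continuous coordinates, the
# single-site discrete kernel for the latent states.
ipm_scalar_block <- function(log_post, x, lcur, j, scale) {
  prop <- x
  prop[j] <- prop[j] + stats::rnorm(1, 0, scale)
  lp <- log_post(prop)
  a <- if (lp == -Inf) 0 else min(1, exp(lp - lcur))
  acc <- stats::runif(1) < a
  list(x = if (acc) prop else x, l = if (acc) lp else lcur, a = a)
}

#' Posterior for the count submodel alone
#'
#' Samples `p_2(alpha0, alpha2, rho, psi_2 | Y_2)`: the count data with the
#' submodel's own priors, no capture-recapture or fecundity information.
#' Used to show how diffuse the shared quantities are without the other
#' submodels.
#'
#' @param data data triple (only `data$counts` is used).
#' @param sweeps retained sweeps.
#' @param warmup discarded sweeps.
#' @param seed integer seed.
#' @return matrix of draws (columns alpha0, alpha2, rho, then psi_2).
#' @export
fit_ipm_count_only <- function(data, sweeps = 3000, warmup = 1000, seed = 1) {
  T <- length(data$counts$y)
  mid <- ipm_submodel_count(data$counts$y, T)
  kern <- ipm_psi2_kernel(T)
  set.seed(derive_seed(seed, 7))
  phi <- c(alpha0 = 0, alpha2 = 0, rho = 2)
  psi2 <- ipm_psi2_start(data$counts$y, T)
  scales <- c(0.8, 0.8, 0.8)  # diffuse target: prior-scale moves
  lcur <- mid$log_joint(phi, psi2)
  total <- warmup + sweeps
  out <- matrix(NA_real_, sweeps, 3 + length(psi2))
  colnames(out) <- c("alpha0", "alpha2", "rho", ipm_psi2_names(T))
  for (i in seq_len(total)) {
    for (j in 1:3) {
      r <- ipm_scalar_block(function(p) mid$log_joint(p, psi2), phi, lcur, j, scales[j])
      phi <- r$x; lcur <- r$l
      if (i <= warmup) scales[j] <- exp(log(scales[j]) + (r$a - 0.44) / max(1, i)^0.6)
    }
    kr <- kern(psi2, phi, mid, i)
    psi2 <- kr$psi2
    lcur <- mid$log_joint(phi, psi2)
    if (i > warmup) out[i - warmup, ] <- c(phi, psi2)
  }
  out
}

#' Direct MCMC on the monolithic joint IPM
#'
#' Targets the joint model with all three likelihoods and a single set of
#' shared priors — the benchmark that the melded posterior under logarithmic
#' pooling with weights (1/2, 1/2, 1/2) reproduces exactly.
#'
#' @param data data triple from [simulate_ipm()].
#' @param sweeps retained sweeps per chain.
#' @param warmup discarded sweeps.
#' @param chains number of chains.
#' @param seed root seed.
#' @return list with `draws` (stacked matrix over chains) and `per_chain`.
#' @export
fit_ipm_joint <- function(data, sweeps = 3000, warmup = 1500, chains = 2, seed = 1) {
  T <- length(data$counts$y)
  cr_sub <- ipm_submodel_cr(data$cr, T)
  mid <- ipm_submodel_count(data$counts$y, T)
  N <- data$fec$N; n <- data$fec$n
  kern <- ipm_psi2_kernel(T)
  # joint log posterior factors; shared priors counted once (they live in the
  # cr and count submodel joints; subtract the duplicated (alpha0, alpha2))
  run_chain <- function(sd) {
    set.seed(sd)
    phi <- c(alpha0 = 0, alpha2 = 0, rho = 2)
    psi1 <- rep(0, T + 1)
    psi2 <- ipm_psi2_start(data$counts$y, T)
    lcr <- function(phi, psi1) cr_sub$log_joint(phi[c("alpha0", "alpha2")], psi1)
    lmid <- function(phi, psi2) mid$log_joint(phi, psi2)
    lfec <- function(rho) fecundity_loglik(N, n, rho)
    ldup <- function(phi) ipm_alpha_lprior(c(phi[["alpha0"]], phi[["alpha2"]])) +
      ipm_rho_lprior(phi[["rho"]])
    lp_phi <- function(phi) lcr(phi, psi1) + lmid(phi, psi2) + lfec(phi[["rho"]]) - ldup(phi)
    scales_phi <- c(0.1, 0.15, 0.1)
    scales_psi1 <- rep(0.2, T + 1)
    lcur <- lp_phi(phi)
    out <- matrix(NA_real_, sweeps, 3 + length(psi1) + length(psi2))
    colnames(out) <- c("alpha0", "alpha2", "rho", cr_sub$psi_names, ipm_psi2_names(T))
    for (i in seq_len(warmup + sweeps)) {
      for (j in 1:3) {
        r <- ipm_scalar_block(lp_phi, phi, lcur, j, scales_phi[j])
        phi <- r$x; lcur <- r$l
        if (i <= warmup) scales_phi[j] <- exp(log(scales_phi[j]) + (r$a - 0.44) / max(1, i)^0.6)
      }
      lcr_cur <- lcr(phi, psi1)
      for (j in seq_along(psi1)) {
        r <- ipm_scalar_block(function(p) lcr(phi, p), psi1, lcr_cur, j, scales_psi1[j])
        psi1 <- r$x; lcr_cur <- r$l
        if (i <= warmup) scales_psi1[j] <- exp(log(scales_psi1[j]) + (r$a - 0.44) / max(1, i)^0.6)
      }
      kr <- kern(psi2, phi, mid, i)
      psi2 <- kr$psi2
      lcur <- lp_phi(phi)
      if (i > warmup) out[i - warmup, ] <- c(phi, psi1, psi2)
    }
    out
  }
  per_chain <- lapply(seq_len(chains), function(cc) run_chain(derive_seed(seed, 30 + cc)))
  list(draws = do.call(rbind, per_chain), per_chain = per_chain)
}
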