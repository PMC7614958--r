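# Little-owls integrated population model: likelihood pieces against direct
# pmf oracles, the simulator, and the chain assembly.

Tt <- 8
coef0 <- list(alpha0 = 0, alpha1 = 0, alpha2 = 0, alpha4 = 0,
              alpha5 = rep(0, Tt - 1), alpha6 = 0)

test_that("link functions map coefficients to valid, structured rates", {
  r <- link_rates(coef0, Tt)
  expect_true(all(r$delta == 0.5))
  expect_true(all(r$pi[, 2:Tt] == 0.5))
  expect_true(all(r$eta == 1))

  cf <- list(alpha0 = -0.8, alpha1 = -0.3, alpha2 = 0.9, alpha4 = 0.2,
             alpha5 = seq(0.1, 0.7, length.out = Tt - 1), alpha6 = -1.2)
  r2 <- link_rates(cf, Tt)
  expect_equal(unname(r2$delta["A", "F", 3]), plogis(cf$alpha0 + cf$alpha2))
  expect_equal(unname(r2$delta["J", "M", 1]), plogis(cf$alpha0 + cf$alpha1))
  expect_equal(unname(r2$pi["M", 4]), plogis(cf$alpha4 + cf$alpha5[3]))
  expect_equal(unname(r2$pi["F", 4]), plogis(cf$alpha5[3]))
  expect_true(all(r2$eta == exp(cf$alpha6)))
  # survival constant over time within a stratum
  expect_equal(r2$delta["J", "F", ], rep(r2$delta["J", "F", 1], Tt))
})

test_that("recapture cell probabilities form simplex rows with the product structure", {
  Q <- recapture_cell_probs(rep(0.5, 3), rep(0.5, 3), 3)
  expect_equal(Q[1, 2], 0.25)
  expect_equal(Q[1, 3], 0.0625)
  set.seed(5)
  delta <- runif(Tt, 0.1, 0.9); pi <- c(NA, runif(Tt - 1, 0.1, 0.9))
  Qr <- recapture_cell_probs(delta, pi, Tt)
  expect_close(rowSums(Qr), rep(1, Tt), 1e-12)
  Qsub <- Qr[, 1:Tt]
  expect_true(all(Qsub[lower.tri(Qsub, diag = TRUE)] == 0))
  # no survival: never recaptured with certainty
  Q0 <- recapture_cell_probs(rep(0, Tt), pi, Tt)
  expect_true(all(Q0[, 1:Tt] == 0))
  expect_true(all(Q0[, Tt + 1] == 1))
})

test_that("capture-recapture log-likelihood equals the direct multinomial pmf", {
  set.seed(6)
  delta <- runif(Tt, 0.2, 0.8); pi <- c(NA, runif(Tt - 1, 0.2, 0.8))
  Q <- recapture_cell_probs(delta, pi, Tt)
  M <- matrix(0L, Tt, Tt + 1)
  for (t in 1:Tt) M[t, ] <- as.integer(rmultinom(1, 30, Q[t, ]))
  cr <- list(M = list(J_F = M), R = list(J_F = rowSums(M)))
  direct <- sum(vapply(1:Tt, function(t) dmultinom(M[t, ], prob = Q[t, ], log = TRUE), 0))
  expect_equal(cr_loglik(cr, list(J_F = Q)), direct, tolerance = 1e-12)

  # zero releases contribute nothing; a single next-year recapture is log Q
  empty <- list(M = list(J_F = matrix(0L, Tt, Tt + 1)),
                R = list(J_F = rep(0L, Tt)))
  expect_equal(cr_loglik(empty, list(J_F = Q)), 0)
  one <- matrix(0L, Tt, Tt + 1); one[2, 3] <- 1L
  expect_equal(cr_loglik(list(M = list(J_F = one), R = list(J_F = rowSums(one))),
                         list(J_F = Q)),
               log(Q[2, 3]), tolerance = 1e-12)
  # positive count on a structural zero
  bad <- matrix(0L, Tt, Tt + 1); bad[3, 2] <- 1L
  expect_identical(cr_loglik(list(M = list(J_F = bad), R = list(J_F = rowSums(bad))),
                             list(J_F = Q)), -Inf)
})

test_that("count log-likelihood composes the Poisson and binomial pieces exactly", {
  T <- 5
  y <- c(4L, 6L, 5L, 7L, 6L)
  xJ <- c(2L, 3L, 2L, 4L, 3L)
  xA1 <- 3L
  sur <- c(NA, 2L, 3L, 2L, 3L)
  imm <- c(NA, 1L, 1L, 2L, 1L)
  rho <- 2.2; dJF <- rep(0.3, T); dAF <- rep(0.55, T); eta <- rep(0.25, T)
  xA <- c(xA1, sur[2:T] + imm[2:T]); x <- xJ + xA
  direct <- sum(dpois(y, x, log = TRUE)) +
    sum(dpois(xJ[2:T], x[1:(T - 1)] * (rho / 2) * dJF[1:(T - 1)], log = TRUE)) +
    sum(dbinom(sur[2:T], x[1:(T - 1)], dAF[1:(T - 1)], log = TRUE)) +
    sum(dpois(imm[2:T], x[1:(T - 1)] * eta[2:T], log = TRUE))
  expect_equal(count_loglik(y, xJ, xA1, sur, imm, rho, dJF, dAF, eta),
               direct, tolerance = 1e-12)

  # extinction: zero population propagates as point masses at zero
  z <- rep(0L, 3)
  expect_equal(count_loglik(c(0L, 0L, 0L), z, 0L, c(NA, 0L, 0L), c(NA, 0L, 0L),
                            rho, rep(.3, 3), rep(.5, 3), rep(.2, 3)), 0)
  expect_identical(count_loglik(c(0L, 0L, 0L), z, 0L, c(NA, 0L, 0L),
                                c(NA, 1L, 0L), rho, rep(.3, 3), rep(.5, 3),
                                rep(.2, 3)), -Inf)
  # more survivors than candidates
  expect_identical(count_loglik(y, xJ, xA1, c(NA, 50L, 3L, 2L, 3L), imm, rho,
                                dJF, dAF, eta), -Inf)
})

test_that("fecundity log-likelihood is the Poisson pmf with its MLE at the count ratio", {
  expect_equal(fecundity_loglik(rep(0L, 4), rep(0L, 4), 1.7), 0)
  expect_equal(fecundity_loglik(10L, 5L, 0.5), dpois(5, 5, log = TRUE))
  expect_identical(fecundity_loglik(c(0L, 3L), c(1L, 2L), 1), -Inf)
  N <- c(12L, 15L, 9L); n <- c(30L, 33L, 25L)
  grid <- seq(0.5, 6, by = 0.001)
  ll <- vapply(grid, function(r) fecundity_loglik(N, n, r), 0)
  expect_lt(abs(grid[which.max(ll)] - sum(n) / sum(N)), 0.002)
})

test_that("the joint prior density penalises and truncates as declared", {
  base <- ipm_log_priors(coef0, rho = 5, xJ1 = 10, xA1 = 25)
  expect_true(is.finite(base))
  bad <- coef0; bad$alpha2 <- 11
  expect_identical(ipm_log_priors(bad, 5, 10, 25), -Inf)
  expect_identical(ipm_log_priors(coef0, 10.5, 10, 25), -Inf)
  expect_identical(ipm_log_priors(coef0, 5, 10, 51), -Inf)
  # uniform pieces contribute their normalising constants
  expect_equal(ipm_log_priors(coef0, 5, 10, 25) -
                 sum(chainmeld:::dtnorm_log(unlist(coef0), 0, 2, -10, 10)),
               log(1 / 10) + 2 * log(1 / 51))
})

test_that("the simulator draws from the stated likelihoods", {
  # strong immigration grows the population
  hot <- ipm_true_state(10); hot$alpha6 <- log(1.2)
  sim_hot <- simulate_ipm(hot, T = 10, releases = 10, seed = 2)
  expect_gt(mean(diff(sim_hot$latents$x)), 0)
  expect_gt(sim_hot$latents$x[10], 3 * sim_hot$latents$x[1])

  # near-zero survival: almost everything lands in the never-recaptured column
  dead <- ipm_true_state(6); dead$alpha0 <- -9; dead$alpha2 <- 0
  sim_dead <- simulate_ipm(dead, T = 6, releases = 200, seed = 3)
  frac_never <- sum(vapply(sim_dead$cr$M, function(m) sum(m[, 7]), 0)) /
    sum(vapply(sim_dead$cr$M, sum, 0))
  expect_gt(frac_never, 0.995)

  # empirical recapture frequencies match the cell probabilities
  truth <- ipm_true_state(5)
  big <- simulate_ipm(truth, T = 5, releases = 20000, seed = 4)
  r <- link_rates(truth, 5)
  Q <- recapture_cell_probs(r$delta["J", "F", ], r$pi["F", ], 5)
  emp <- big$cr$M$J_F / 20000
  tol <- 4 * sqrt(Q * (1 - Q) / 20000) + 1e-9
  expect_true(all(abs(emp - Q) < tol))

  # release totals are row sums and structural zeros hold
  expect_true(all(vapply(seq_along(big$cr$M), function(i)
    all(rowSums(big$cr$M[[i]]) == big$cr$R[[i]]), TRUE)))
})

test_that("chain assembly reproduces the stated pooled priors", {
  data <- simulate_ipm(T = 6, releases = 20, seed = 9)
  logm <- build_ipm_chain(data, "logarithmic")
  poe <- build_ipm_chain(data, "poe")
  lin <- build_ipm_chain(data, "linear")
  expect_length(validate_chain(logm$chain$submodels), 0)

  tn <- function(x) chainmeld:::dtnorm_log(x, 0, 2, -10, 10)
  for (p in list(c(alpha0 = 0.5, alpha2 = -1, rho = 3),
                 c(alpha0 = -2, alpha2 = 2, rho = 8))) {
    shared <- tn(p[["alpha0"]]) + tn(p[["alpha2"]]) + dunif(p[["rho"]], 0, 10, log = TRUE)
    # matched-weight logarithmic and equal-weight linear pooling reproduce the
    # common submodel priors; PoE doubles every log factor
    expect_equal(pooled_eval(logm$pooled, p), shared, tolerance = 1e-12)
    expect_equal(pooled_eval(lin$pooled, p), shared, tolerance = 1e-12)
    expect_equal(pooled_eval(poe$pooled, p), 2 * shared, tolerance = 1e-12)
  }
  # PoE squares the truncated normal: more concentrated around zero
  g_poe <- riemann1(function(a) pooled_eval(poe$pooled, c(alpha0 = a, alpha2 = 0, rho = 5)),
                    lims = c(-10, 10), n = 2001)
  p_poe <- exp(g_poe$lv - g_poe$logZ)
  var_poe <- sum(g_poe$ax^2 * p_poe) / sum(p_poe)
  expect_lt(var_poe, 4 * 0.6)  # well below the prior variance of 2^2
})

test_that("melding with matched priors equals the monolithic joint IPM density", {
  data <- simulate_ipm(T = 6, releases = 20, seed = 10)
  built <- build_ipm_chain(data, "logarithmic")
  model <- melded_model(built$chain, built$pooled)
  T <- 6
  set.seed(11)
  diffs <- replicate(50, {
    phi <- c(alpha0 = rnorm(1, 0, 1), alpha2 = rnorm(1, 0, 1), rho = runif(1, 1, 4))
    psi1 <- c(rnorm(2, 0, 0.5), rnorm(T - 1, 0.5, 0.3))
    lat <- list(xJ = rpois(T, 8), xA1 = rpois(1, 10),
                sur = c(NA, rpois(T - 1, 5)), imm = c(NA, rpois(T - 1, 3)))
    psi2 <- chainmeld:::ipm_pack_psi2(rnorm(1, -1.5, 0.3), lat$xJ, lat$xA1,
                                      lat$sur, lat$imm)
    meld <- melded_log_density(model, phi, list(psi1, psi2, numeric(0)))
    cf <- list(alpha0 = phi[["alpha0"]], alpha1 = psi1[1], alpha2 = phi[["alpha2"]],
               alpha4 = psi1[2], alpha5 = psi1[3:(T + 1)], alpha6 = psi2[1])
    r <- link_rates(cf, T)
    Q <- list()
    for (a in c("J", "A")) for (s in c("F", "M"))
      Q[[paste(a, s, sep = "_")]] <- recapture_cell_probs(r$delta[a, s, ], r$pi[s, ], T)
    joint <- ipm_log_priors(cf, phi[["rho"]], lat$xJ[1], lat$xA1) +
      cr_loglik(data$cr, Q) +
      count_loglik(data$counts$y, lat$xJ, lat$xA1, lat$sur, lat$imm,
                   phi[["rho"]], r$delta["J", "F", ], r$delta["A", "F", ], r$eta) +
      fecundity_loglik(data$fec$N, data$fec$n, phi[["rho"]])
    meld - joint
  })
  finite <- is.finite(diffs)
  expect_gt(sum(finite), 25)
  expect_lt(diff(range(diffs[finite])), 1e-9)
})

test_that("the melded posterior is far tighter than the count-only posterior", {
  data <- simulate_ipm(T = 12, releases = 40, seed = 12)
  fit <- fit_ipm_meld(data, n_stage1 = 800, sweeps = 800, chains = 1, seed = 2,
                      stage1_warmup = 2000, stage1_thin = 2)
  co <- fit_ipm_count_only(data, sweeps = 800, warmup = 400, seed = 2)
  for (p in c("alpha0", "alpha2", "rho")) {
    w_meld <- diff(quantile(fit$draws[, p], c(0.025, 0.975)))
    w_count <- diff(quantile(co[, p], c(0.025, 0.975)))
    expect_lt(w_meld, w_count)
  }
  # truth should sit inside the (wide) melded 95% intervals here
  tr <- c(alpha0 = data$truth$alpha0, alpha2 = data$truth$alpha2,
          rho = data$truth$rho)
  for (p in names(tr)) {
    q <- quantile(fit$draws[, p], c(0.005, 0.995))
    expect_gt(tr[[p]], q[1]); expect_lt(tr[[p]], q[2])
  }
})
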