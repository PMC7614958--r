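# Stage-one targets, block acceptance probabilities, and the stage-two
# Metropolis-within-Gibbs sampler, checked against conjugate and enumeration
# oracles.

gdata <- simulate_gaussian_chain(seed = 21)
gb <- build_gaussian_chain(gdata)
ddemo <- discrete_chain_demo(seed = 3)

test_that("subprior-sides stage-one target is the ordinary subposterior", {
  tgt <- stage_one_target(gb$submodels[[1]], gb$pooled$factors$left)
  for (x in list(c(0.5, -0.2), c(-1, 1), c(2, 0.3))) {
    expect_equal(tgt(x), gb$submodels[[1]]$log_joint(c(a = x[1]), x[2]),
                 tolerance = 1e-12)
  }
})

test_that("flat-sides stage-one target divides out the submodel prior marginal", {
  flat <- decompose_pooled(gb$pooled, "flat-sides")
  tgt <- stage_one_target(gb$submodels[[1]], flat$factors$left)
  sub <- gb$submodels[[1]]
  for (x in list(c(0.5, -0.2), c(-1, 1))) {
    expect_equal(tgt(x),
                 sub$log_joint(c(a = x[1]), x[2]) - sub$log_phi_marginal(c(a = x[1])),
                 tolerance = 1e-12)
  }
})

test_that("stage-one draws from a conjugate side model match the closed form", {
  s1 <- sample_stage_one(gb$submodels[[1]], gb$pooled$factors$left,
                         n_keep = 4000, warmup = 3000, seed = 5)
  exact <- gaussian_side_exact(gdata$y1)
  x <- cbind(s1$phi[, 1], s1$psi[, 1])
  for (j in 1:2) {
    se <- mcse_mean(x[, j])
    expect_lt(abs(mean(x[, j]) - exact$mean[j]), 3 * se)
    expect_lt(abs(var(x[, j]) / exact$cov[j, j] - 1), 0.15)
  }
  expect_error(
    sample_stage_one(
      submodel_spec("bad", function(phi, psi) -Inf, function(phi) 0,
                    phi_right = "a", phi_init = c(a = 0)),
      n_keep = 10),
    "initialisation error")
})

test_that("side acceptance probabilities match brute-force table ratios", {
  tb <- ddemo$tables
  mid <- ddemo$submodels[[2]]
  pm <- ddemo$pooled$factors$middle
  # hand ratio straight from the tables.  The melded posterior is
  # proportional to q1 L1 q2 L2 r2 q3 L3 and side-1 proposals come from
  # s1 = q1 L1, so the Metropolis ratio for i* against i reduces to
  # q2(i*, j) L2(i*, j, k) / (q2(i, j) L2(i, j, k)).
  hand_side1 <- function(ip, ic, j, k) {
    num <- tb$q2[ip + 1, j + 1] * tb$L2[ip + 1, j + 1, k + 1]
    den <- tb$q2[ic + 1, j + 1] * tb$L2[ic + 1, j + 1, k + 1]
    min(1, num / den)
  }
  for (ip in 0:2) for (ic in 0:2) for (j in 0:2) for (k in 0:2) {
    expect_equal(
      accept_prob_side1(c(i = ip), c(i = ic), mid, pm, c(j = j), k),
      hand_side1(ip, ic, j, k), tolerance = 1e-12)
  }
  # proposal identical to current state
  expect_equal(accept_prob_side1(c(i = 1), c(i = 1), mid, pm, c(j = 0), 2), 1)
  expect_equal(accept_prob_side3(c(j = 2), c(j = 2), mid, pm, c(i = 0), 1), 1)
})

test_that("side-3 acceptance equals side-1 acceptance on the mirrored chain", {
  tb <- ddemo$tables
  mid <- ddemo$submodels[[2]]
  pm <- ddemo$pooled$factors$middle
  # mirrored chain: swap the roles of i and j everywhere
  mid_rev <- submodel_spec(
    "middle-rev",
    log_joint = function(phi, psi)
      log(tb$q2[phi[["i"]] + 1, phi[["j"]] + 1]) + log(tb$r2[psi + 1]) +
      log(tb$L2[phi[["i"]] + 1, phi[["j"]] + 1, psi + 1]),
    log_phi_marginal = function(phi) log(tb$q2[phi[["i"]] + 1, phi[["j"]] + 1]),
    phi_left = "j", phi_right = "i", psi_init = 0)
  dc2r <- density_component(function(x) log(tb$q2[x[2] + 1, x[1] + 1]), c("j", "i"))
  dc1 <- density_component(function(x) log(tb$q1[x + 1]), "i")
  dc3 <- density_component(function(x) log(tb$q3[x + 1]), "j")
  pooled_rev <- decompose_pooled(pool_log(list(dc3, dc2r, dc1), c(1, 1, 1)),
                                 "subprior-sides", side_priors = list(dc3, dc1))
  pm_rev <- pooled_rev$factors$middle
  for (jp in 0:2) for (jc in 0:2) for (i in 0:2) for (k in 0:2) {
    expect_equal(
      accept_prob_side3(c(j = jp), c(j = jc), mid, pm, c(i = i), k),
      accept_prob_side1(c(j = jp), c(j = jc), mid_rev, pm_rev, c(i = i), k),
      tolerance = 1e-12)
  }
})

test_that("psi2 kernel has the middle conditional as stationary distribution", {
  mid <- ddemo$submodels[[2]]
  phi <- c(i = 1, j = 2)
  # uniform-proposal MH kernel matrix over k in {0,1,2}
  K <- matrix(0, 3, 3)
  for (k in 0:2) for (kp in 0:2) if (kp != k) {
    K[k + 1, kp + 1] <- (1 / 3) * accept_prob_psi2(kp, k, mid, phi)
  }
  diag(K) <- 1 - rowSums(K)
  target <- vapply(0:2, function(k) exp(mid$log_joint(phi, k)), 0)
  target <- target / sum(target)
  e <- eigen(t(K))
  stat <- Re(e$vectors[, which.max(Re(e$values))])
  stat <- stat / sum(stat)
  expect_close(stat, target, 1e-12)
  expect_close(drop(target %*% K), target, 1e-14)
  # symmetric random-walk with identical proposal accepts surely
  expect_equal(accept_prob_psi2(0.4, 0.4,
                                submodel_spec("g", function(phi, psi)
                                  dnorm(psi, log = TRUE), function(phi) 0,
                                  phi_right = "x"),
                                c(x = 0)), 1)
})

test_that("small-step random walks on a smooth middle model accept almost surely", {
  mid <- gb$submodels[[2]]
  phi <- c(a = 0.2, b = -0.1)
  accs <- vapply(c(1e-2, 1e-4, 1e-6), function(h) {
    set.seed(1)
    mean(replicate(200, accept_prob_psi2(0.3 + rnorm(1, 0, h), 0.3, mid, phi)))
  }, 0)
  expect_true(all(diff(accs) > 0) || accs[3] > 0.999)
  expect_gt(accs[3], 0.999)
})

test_that("two-stage sampling reproduces the conjugate Gaussian joint posterior", {
  s1 <- sample_stage_one(gb$submodels[[1]], gb$pooled$factors$left,
                         n_keep = 4000, warmup = 4000, thin = 5, seed = 31)
  s3 <- sample_stage_one(gb$submodels[[3]], gb$pooled$factors$right,
                         n_keep = 4000, warmup = 4000, thin = 5, seed = 33)
  ch <- run_stage_two_chains(s1, s3, gb$submodels[[2]], gb$pooled,
                             chains = 4, seed = 35, sweeps = 4000)
  exact <- gaussian_chain_exact_posterior(gdata)
  draws <- combine_chains(ch)
  psi1 <- do.call(rbind, lapply(ch, `[[`, "psi1"))
  psi3 <- do.call(rbind, lapply(ch, `[[`, "psi3"))
  full <- cbind(draws[, c("a", "b")], psi1[, 1], draws[, "psi2"], psi3[, 1])
  for (j in 1:5) {
    per_chain <- lapply(seq_along(ch), function(cc)
      full[seq((cc - 1) * 4000 + 1, cc * 4000), j])
    se <- mcse_mean(per_chain)
    expect_lt(abs(mean(full[, j]) - exact$mean[j]), 3.5 * se)
    expect_lt(abs(var(full[, j]) / exact$cov[j, j] - 1), 0.15)
  }
})

test_that("stage-two output reattaches stage-one rows verbatim", {
  s1 <- sample_stage_one(gb$submodels[[1]], gb$pooled$factors$left,
                         n_keep = 500, warmup = 500, seed = 41)
  s3 <- sample_stage_one(gb$submodels[[3]], gb$pooled$factors$right,
                         n_keep = 500, warmup = 500, seed = 43)
  out <- run_stage_two(s1, s3, gb$submodels[[2]], gb$pooled, sweeps = 400,
                       seed = 45)
  expect_identical(unname(out$draws[, "a"]), unname(s1$phi[out$indices[, "n1"], 1]))
  expect_identical(unname(out$draws[, "b"]), unname(s3$phi[out$indices[, "n3"], 1]))
  expect_identical(unname(out$psi1[, 1]), unname(s1$psi[out$indices[, "n1"], 1]))
  expect_identical(unname(out$psi3[, 1]), unname(s3$psi[out$indices[, "n3"], 1]))
})

test_that("acceptance ratios are invariant to rescaling unnormalised factors", {
  s1 <- sample_stage_one(gb$submodels[[1]], gb$pooled$factors$left,
                         n_keep = 300, warmup = 300, seed = 51)
  s3 <- sample_stage_one(gb$submodels[[3]], gb$pooled$factors$right,
                         n_keep = 300, warmup = 300, seed = 53)
  run <- function(pooled) run_stage_two(s1, s3, gb$submodels[[2]], pooled,
                                        sweeps = 300, seed = 55)$draws
  shifted <- gb$pooled
  mid <- shifted$factors$middle$component
  shifted$factors$middle$component <-
    density_component(function(x) mid$log_density(x) + 37.5, mid$vars,
                      proper = FALSE)
  expect_identical(run(gb$pooled), run(shifted))
})

test_that("a single-row stage-one side degenerates gracefully", {
  s1 <- sample_stage_one(gb$submodels[[1]], gb$pooled$factors$left,
                         n_keep = 300, warmup = 300, seed = 61)
  s1$phi <- s1$phi[1, , drop = FALSE]
  s1$psi <- s1$psi[1, , drop = FALSE]
  s3 <- sample_stage_one(gb$submodels[[3]], gb$pooled$factors$right,
                         n_keep = 300, warmup = 300, seed = 63)
  out <- suppressWarnings(
    run_stage_two(s1, s3, gb$submodels[[2]], gb$pooled, sweeps = 500, seed = 65))
  expect_equal(unique(out$draws[, "a"]), unname(s1$phi[1, 1]))
  expect_gt(length(unique(out$draws[, "b"])), 10)
  expect_gt(length(unique(out$draws[, "psi2"])), 10)
})

test_that("matched-prior melding equals direct MCMC on the natural joint model", {
  # logarithmic pooling with matching priors makes the melded model the joint
  # model; compare stage-two moments with a direct random-walk fit
  joint_lp <- function(x) {
    phi <- c(a = x[1], b = x[2])
    melded_log_density(melded_model(gb$chain, gb$pooled), phi,
                       list(x[3], x[4], x[5]))
  }
  direct <- mh_sample(joint_lp, init = rep(0, 5), n_keep = 6000, warmup = 3000,
                      seed = 71)
  s1 <- sample_stage_one(gb$submodels[[1]], gb$pooled$factors$left,
                         n_keep = 3000, warmup = 2000, seed = 72)
  s3 <- sample_stage_one(gb$submodels[[3]], gb$pooled$factors$right,
                         n_keep = 3000, warmup = 2000, seed = 73)
  out <- run_stage_two(s1, s3, gb$submodels[[2]], gb$pooled, sweeps = 6000,
                       seed = 74)
  for (j in 1:2) {
    se <- sqrt(mcse_mean(direct$draws[, j])^2 + mcse_mean(out$draws[, j])^2)
    expect_lt(abs(mean(direct$draws[, j]) - mean(out$draws[, j])), 3.5 * se)
  }
})
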