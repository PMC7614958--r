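# The two-stage parallel sampler for the chained melded posterior (M = 3).
#
# Stage one draws, independently and in parallel, from the prior-adjusted
# subposteriors of submodels 1 and 3.  Stage two runs a Metropolis-within-
# Gibbs sweep over (phi_{1^2}, psi_1), (phi_{2^3}, psi_3) and psi_2, where the
# side updates propose rows of the stage-one draws by uniform index; the
# acceptance ratios involve only the middle submodel and the middle pooled
# factor, so neither psi_1 nor psi_3 is ever re-evaluated in stage two.

#' Generic adaptive random-walk Metropolis sampler
#'
#' Joint Gaussian random-walk proposals with per-coordinate scales and a
#' global step size adapted towards a target acceptance rate during warmup
#' only (frozen afterwards, so the stationary distribution is untouched).
#'
#' @param log_target function of a numeric vector returning an (unnormalised)
#'   log-density.
#' @param init numeric vector, must have finite log-density.
#' @param n_keep retained draws after warmup and thinning.
#' @param warmup warmup iterations (discarded).
#' @param thin keep every `thin`-th post-warmup draw.
#' @param scale initial per-coordinate proposal scales (default 0.5).
#' @param target_accept adaptation target (default 0.234 for joint updates).
#' @param seed optional integer seed.
#' @return list with `draws` (n_keep x d matrix), `accept_rate`, and the
#'   frozen `scale`.
#' @export
mh_sample <- function(log_target, init, n_keep, warmup = n_keep, thin = 1,
                      scale = NULL, target_accept = 0.234, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(init)
  x <- as.numeric(init)
  lt <- log_target(x)
  if (!is.finite(lt))
    stop("initialisation error: log-target not finite at the initial point")
  sd_vec <- if (is.null(scale)) rep(0.5, d) else rep(scale, length.out = d)
  ls <- 0                      # log global step multiplier
  # Welford accumulators for per-coordinate spread (second half of warmup)
  wn <- 0; wmean <- numeric(d); wm2 <- numeric(d)
  total <- warmup + n_keep * thin
  draws <- matrix(NA_real_, n_keep, d)
  acc <- 0L; kept <- 0L
  for (i in seq_len(total)) {
    prop <- x + exp(ls) * sd_vec * stats::rnorm(d)
    ltp <- log_target(prop)
    a <- if (ltp == -Inf) 0 else min(1, exp(ltp - lt))
    if (stats::runif(1) < a) { x <- prop; lt <- ltp; acc <- acc + 1L }
    if (i <= warmup) {
      ls <- ls + (a - target_accept) / max(1, i)^0.6
      if (i > warmup / 4 && i <= 3 * warmup / 4) {
        wn <- wn + 1
        dlt <- x - wmean
        wmean <- wmean + dlt / wn
        wm2 <- wm2 + dlt * (x - wmean)
      }
      if (i == ceiling(3 * warmup / 4) && wn > d + 1) {
        s <- sqrt(wm2 / (wn - 1))
        # reshape the proposal to the estimated marginal spreads; the global
        # log-step keeps adapting for the rest of warmup
        if (all(s > 0)) { sd_vec <- s; ls <- log(2.38 / sqrt(d)) }
      }
    } else if ((i - warmup) %% thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- x
    }
  }
  list(draws = draws, accept_rate = acc / total,
       scale = exp(ls) * sd_vec)
}

#' Build a stage-one target from a submodel and a pooled side factor
#'
#' The stage-one target for side m in {1, 3} is
#' `p_pool,m(phi_m) p_m(phi_m, psi_m, Y_m) / p_m(phi_m)`.  With subprior-sides
#' decomposition (`p_pool,m = p_m`) the ratio cancels and the target is the
#' ordinary subposterior; with flat sides the submodel prior marginal is
#' divided out.
#'
#' @param sub a [submodel_spec()] (an end submodel).
#' @param pooled_side the left or right factor of a decomposed pooled prior
#'   (element of `pooled$factors`), or `NULL` for a flat factor.
#' @return function of `c(phi, psi)` returning the log target.
#' @export
stage_one_target <- function(sub, pooled_side = NULL) {
  d_phi <- length(sub$phi_vars)
  vars <- sub$phi_vars
  flat <- is.null(pooled_side) || isTRUE(pooled_side$flat)
  subprior <- FALSE
  if (!flat && identical(pooled_side$component$log_density, sub$log_phi_marginal))
    subprior <- TRUE
  function(x) {
    phi <- stats::setNames(x[seq_len(d_phi)], vars)
    psi <- x[-seq_len(d_phi)]
    lj <- sub$log_joint(phi, psi)
    if (lj == -Inf) return(-Inf)
    if (subprior) return(lj)
    lm <- sub$log_phi_marginal(phi)
    if (lm == -Inf) return(-Inf)
    lp <- if (flat) 0 else dc_eval(pooled_side$component, phi)
    lp + lj - lm
  }
}

#' Stage one: sample a side subposterior
#'
#' @param sub end [submodel_spec()] (side 1 or 3 of the chain).
#' @param pooled_side matching side factor from the decomposed pooled prior
#'   (or `NULL` for flat).
#' @param n_keep,warmup,thin,scale,seed passed to [mh_sample()]; ignored when
#'   the submodel supplies a direct `sampler` and the side factor makes the
#'   target the plain subposterior.
#' @param use_direct use the submodel's direct sampler when available
#'   (requires a flat-cancelling target, i.e. subprior-sides mode).
#' @return object of class `stage_one_draws`: `phi` (matrix, overlap
#'   coordinates), `psi` (matrix, possibly 0 columns), acceptance rate and
#'   provenance.
#' @export
sample_stage_one <- function(sub, pooled_side = NULL, n_keep = 5000,
                             warmup = n_keep, thin = 1, scale = NULL,
                             seed = NULL, use_direct = !is.null(sub$sampler)) {
  d_phi <- length(sub$phi_vars)
  if (use_direct && !is.null(sub$sampler)) {
    m <- sub$sampler(n_keep, seed)
    if (anyNA(m) || any(!is.finite(m))) stop("direct sampler returned non-finite draws")
    out <- list(phi = m[, seq_len(d_phi), drop = FALSE],
                psi = m[, -seq_len(d_phi), drop = FALSE],
                accept_rate = NA_real_,
                provenance = list(method = "direct", n = n_keep, seed = seed,
                                  thin = 1L, warmup = 0L))
  } else {
    init <- c(sub$phi_init %||% rep(0, d_phi), sub$psi_init %||% numeric(0))
    tgt <- stage_one_target(sub, pooled_side)
    fit <- mh_sample(tgt, init, n_keep = n_keep, warmup = warmup, thin = thin,
                     scale = scale, seed = seed)
    out <- list(phi = fit$draws[, seq_len(d_phi), drop = FALSE],
                psi = fit$draws[, -seq_len(d_phi), drop = FALSE],
                accept_rate = fit$accept_rate,
                provenance = list(method = "rwm", n = n_keep, seed = seed,
                                  thin = as.integer(thin), warmup = as.integer(warmup)))
  }
  colnames(out$phi) <- sub$phi_vars
  if (ncol(out$psi) > 0 && length(sub$psi_names) == ncol(out$psi))
    colnames(out$psi) <- sub$psi_names
  if (nrow(out$phi) < 1) stop("stage one produced no draws")
  if (anyNA(out$phi) || any(!is.finite(out$phi))) stop("non-finite stage-one draws")
  class(out) <- "stage_one_draws"
  out
}

# Shared core of the two side acceptance ratios (Metropolis ratio built from
# the middle submodel joint, the middle submodel prior marginal, and the
# middle pooled factor; all other terms cancel against the proposal).
side_log_ratio <- function(middle, pool_mid, phi_prop, phi_cur, psi2) {
  lj_cur <- middle$log_joint(phi_cur, psi2)
  lm_cur <- middle$log_phi_marginal(phi_cur)
  lp_cur <- dc_eval(pool_mid$component, phi_cur)
  if (!is.finite(lj_cur - lm_cur + lp_cur))
    stop("invalid-state: middle-submodel density is zero at the current state")
  lj_p <- middle$log_joint(phi_prop, psi2)
  if (lj_p == -Inf) return(-Inf)
  lm_p <- middle$log_phi_marginal(phi_prop)
  lp_p <- dc_eval(pool_mid$component, phi_prop)
  (lp_p + lj_p - lm_p) - (lp_cur + lj_cur - lm_cur)
}

#' Acceptance probability for the side-1 block
#'
#' Probability of accepting a stage-one proposal `(phi_{1^2}*, psi_1*)` against
#' the current `(phi_{1^2}, psi_1)`, holding `phi_{2^3}` and `psi_2` fixed.
#' Only middle-submodel and middle-pooled-factor terms appear, so the value is
#' independent of psi_1 and psi_3.
#'
#' @param phi12_prop,phi12_cur named numeric vectors over the left overlap.
#' @param middle the middle [submodel_spec()].
#' @param pool_mid middle factor of the decomposed pooled prior
#'   (`pooled$factors$middle`).
#' @param phi23 named numeric vector, current right overlap value.
#' @param psi2 current psi_2.
#' @return acceptance probability in \[0, 1\].
#' @export
accept_prob_side1 <- function(phi12_prop, phi12_cur, middle, pool_mid,
                              phi23, psi2) {
  prop <- c(phi12_prop, phi23)
  cur <- c(phi12_cur, phi23)
  min(1, exp(side_log_ratio(middle, pool_mid, prop, cur, psi2)))
}

#' Acceptance probability for the side-3 block
#'
#' Mirror of [accept_prob_side1()] with the left overlap held fixed.
#' @param phi23_prop,phi23_cur named numeric vectors over the right overlap.
#' @inheritParams accept_prob_side1
#' @param phi12 named numeric vector, current left overlap value.
#' @export
accept_prob_side3 <- function(phi23_prop, phi23_cur, middle, pool_mid,
                              phi12, psi2) {
  prop <- c(phi12, phi23_prop)
  cur <- c(phi12, phi23_cur)
  min(1, exp(side_log_ratio(middle, pool_mid, prop, cur, psi2)))
}

#' Acceptance probability for the psi_2 block
#'
#' `min(1, p_2(phi, psi_2*, Y_2) q(psi_2 | psi_2*) /
#'         (p_2(phi, psi_2, Y_2) q(psi_2* | psi_2)))`; for a symmetric
#' proposal the q terms cancel (pass `log_q = NULL`).
#'
#' @param psi2_prop,psi2_cur numeric vectors.
#' @param middle the middle [submodel_spec()].
#' @param phi named numeric vector over both overlaps.
#' @param log_q optional function `(to, from)` giving `log q(to | from)`.
#' @export
accept_prob_psi2 <- function(psi2_prop, psi2_cur, middle, phi, log_q = NULL) {
  lj_cur <- middle$log_joint(phi, psi2_cur)
  if (lj_cur == -Inf) stop("invalid-state: middle density zero at current psi_2")
  lr <- middle$log_joint(phi, psi2_prop) - lj_cur
  if (!is.null(log_q)) {
    lq_rev <- log_q(psi2_cur, psi2_prop)
    lq_fwd <- log_q(psi2_prop, psi2_cur)
    if (lq_fwd == -Inf) stop("proposal-support error: q is zero at the proposed move")
    lr <- lr + lq_rev - lq_fwd
  }
  min(1, exp(lr))
}

#' Stage two: Metropolis-within-Gibbs on the melded posterior
#'
#' One sweep updates, in order: the side-1 pair by a uniform stage-one index
#' proposal, the side-3 pair likewise, then psi_2 (Gaussian random walk by
#' default, or a user kernel).  Accepted indices are stored so psi_1 and psi_3
#' can be reattached verbatim from the stage-one arrays.
#'
#' @param side1,side3 `stage_one_draws` for submodels 1 and 3.
#' @param middle the middle [submodel_spec()].
#' @param pooled a decomposed `pooled_prior` (see [decompose_pooled()]); only
#'   its middle factor enters the stage-two ratios.
#' @param sweeps retained sweeps per chain.
#' @param warmup discarded initial sweeps (default 10% of `sweeps`).
#' @param psi2_init initial psi_2 (default the middle submodel's `psi_init`).
#' @param psi2_kernel `NULL` for the adaptive Gaussian random walk, or a
#'   function `(psi2, phi, middle, sweep)` returning
#'   `list(psi2 = ..., accepted = <number of accepted component moves>,
#'   attempts = <number attempted>)` implementing a valid kernel for
#'   `p_2(phi, psi_2, Y_2)` at fixed phi.
#' @param psi2_scale initial random-walk scales for the default kernel.
#' @param block_order `"fixed"` (side1, side3, psi2) or `"random"` scan.
#' @param seed integer seed for this chain's stream.
#' @param mixing_window if every proposal in a window of this many sweeps is
#'   rejected for some block, a mixing warning is raised (not an error).
#' @param log_every emit one structured log line per block every this many
#'   sweeps (0 = silent, the default).
#' @return object of class `melded_draws`: matrix `draws` with columns
#'   (left overlap, right overlap, psi_2), matrices `psi1`, `psi3` reattached
#'   by index, `indices` (n1, n3 traces) and per-block acceptance rates.
#' @export
run_stage_two <- function(side1, side3, middle, pooled, sweeps = 5000,
                          warmup = max(1L, round(0.1 * sweeps)),
                          psi2_init = NULL, psi2_kernel = NULL,
                          psi2_scale = 0.5, block_order = c("fixed", "random"),
                          seed = NULL, mixing_window = 1000, log_every = 0) {
  block_order <- match.arg(block_order)
  if (!is.null(seed)) set.seed(seed)
  pool_mid <- pooled$factors$middle
  if (is.null(pool_mid)) stop("pooled prior has no decomposition; call decompose_pooled()")
  v1 <- colnames(side1$phi); v3 <- colnames(side3$phi)
  N1 <- nrow(side1$phi); N3 <- nrow(side3$phi)
  n1 <- sample.int(N1, 1); n3 <- sample.int(N3, 1)
  phi12 <- stats::setNames(side1$phi[n1, ], v1)
  phi23 <- stats::setNames(side3$phi[n3, ], v3)
  psi2 <- psi2_init %||% middle$psi_init %||% numeric(0)
  d2 <- length(psi2)
  phi <- c(phi12, phi23)
  lj <- middle$log_joint(phi, psi2)
  lm <- middle$log_phi_marginal(phi)
  lp <- dc_eval(pool_mid$component, phi)
  if (!is.finite(lj - lm + lp)) {
    # scan stage-one rows for a jointly feasible start
    ok <- FALSE
    for (trial in seq_len(min(200, N1 * N3))) {
      n1 <- sample.int(N1, 1); n3 <- sample.int(N3, 1)
      phi <- c(stats::setNames(side1$phi[n1, ], v1), stats::setNames(side3$phi[n3, ], v3))
      lj <- middle$log_joint(phi, psi2); lm <- middle$log_phi_marginal(phi)
      lp <- dc_eval(pool_mid$component, phi)
      if (is.finite(lj - lm + lp)) { ok <- TRUE; break }
    }
    if (!ok) stop("initialisation error: no finite starting state found")
    phi12 <- phi[v1]; phi23 <- phi[v3]
  }
  # pre-named stage-one rows: avoids per-sweep setNames in the hot loop
  rows1 <- lapply(seq_len(N1), function(r) stats::setNames(side1$phi[r, ], v1))
  rows3 <- lapply(seq_len(N3), function(r) stats::setNames(side3$phi[r, ], v3))
  use_rw <- is.null(psi2_kernel) && d2 > 0
  rw_scale <- rep(psi2_scale, length.out = max(d2, 1))
  rw_target <- if (d2 == 1) 0.44 else 0.234
  rw_ls <- 0
  total <- warmup + sweeps
  draws <- matrix(NA_real_, sweeps, length(v1) + length(v3) + d2)
  colnames(draws) <- c(v1, v3, if (d2 > 0) {
    if (length(middle$psi_names) == d2) middle$psi_names else paste0("psi2[", seq_len(d2), "]")
  })
  idx <- matrix(NA_integer_, sweeps, 2, dimnames = list(NULL, c("n1", "n3")))
  acc <- c(side1 = 0, side3 = 0, psi2 = 0)
  att <- c(side1 = 0, side3 = 0, psi2 = 0)
  last_acc <- c(side1 = 0L, side3 = 0L, psi2 = 0L)
  warned <- FALSE
  cur_term <- function() lp + lj - lm   # cached middle-block log factor
  upd_side <- function(which_side) {
    if (which_side == 1L) {
      np <- sample.int(N1, 1)
      phip <- c(rows1[[np]], phi23)
    } else {
      np <- sample.int(N3, 1)
      phip <- c(phi12, rows3[[np]])
    }
    lj_p <- middle$log_joint(phip, psi2)
    if (lj_p == -Inf) return(FALSE)
    lm_p <- middle$log_phi_marginal(phip)
    lp_p <- dc_eval(pool_mid$component, phip)
    lr <- (lp_p + lj_p - lm_p) - (lp + lj - lm)
    if (log(stats::runif(1)) < lr) {
      lj <<- lj_p; lm <<- lm_p; lp <<- lp_p
      if (which_side == 1L) { n1 <<- np; phi12 <<- phip[v1] }
      else { n3 <<- np; phi23 <<- phip[v3] }
      TRUE
    } else FALSE
  }
  upd_psi2 <- function(i) {
    if (d2 == 0) return(NA)
    phi_now <- c(phi12, phi23)
    if (use_rw) {
      prop <- psi2 + exp(rw_ls) * rw_scale * stats::rnorm(d2)
      lj_p <- middle$log_joint(phi_now, prop)
      a <- if (lj_p == -Inf) 0 else min(1, exp(lj_p - lj))
      if (i <= warmup) rw_ls <<- rw_ls + (a - rw_target) / max(1, i)^0.6
      if (stats::runif(1) < a) { psi2 <<- prop; lj <<- lj_p; return(TRUE) }
      return(FALSE)
    }
    res <- psi2_kernel(psi2, phi_now, middle, i)
    psi2 <<- res$psi2
    lj <<- middle$log_joint(phi_now, psi2)
    acc["psi2"] <<- acc["psi2"] + res$accepted
    att["psi2"] <<- att["psi2"] + res$attempts
    res$accepted > 0
  }
  for (i in seq_len(total)) {
    blocks <- if (block_order == "fixed") 1:3 else sample(1:3)
    for (b in blocks) {
      if (b == 1L) {
        att["side1"] <- att["side1"] + 1
        if (upd_side(1L)) { acc["side1"] <- acc["side1"] + 1; last_acc["side1"] <- i }
      } else if (b == 2L) {
        att["side3"] <- att["side3"] + 1
        if (upd_side(3L)) { acc["side3"] <- acc["side3"] + 1; last_acc["side3"] <- i }
      } else {
        ok <- upd_psi2(i)
        if (use_rw) {
          att["psi2"] <- att["psi2"] + 1
          if (isTRUE(ok)) { acc["psi2"] <- acc["psi2"] + 1; last_acc["psi2"] <- i }
        } else if (isTRUE(ok)) last_acc["psi2"] <- i
      }
    }
    if (log_every > 0 && i %% log_every == 0) {
      for (b in names(att)) {
        message(sprintf("sweep=%d block=%s accept=%.3f", i, b,
                        if (att[b] > 0) acc[b] / att[b] else NA_real_))
      }
    }
    if (!warned && i - min(last_acc[c("side1", "side3")]) > mixing_window) {
      warning("mixing-failure: a stage-two block rejected every proposal in a ",
              "window of ", mixing_window, " sweeps")
      warned <- TRUE
    }
    if (i > warmup) {
      k <- i - warmup
      draws[k, ] <- c(phi12, phi23, psi2)
      idx[k, ] <- c(n1, n3)
    }
  }
  out <- list(draws = draws, indices = idx,
              psi1 = side1$psi[idx[, "n1"], , drop = FALSE],
              psi3 = side3$psi[idx[, "n3"], , drop = FALSE],
              accept_rates = ifelse(att > 0, acc / att, NA_real_),
              warmup = warmup, seed = seed)
  class(out) <- "melded_draws"
  out
}

#' Run multiple stage-two chains
#'
#' @inheritParams run_stage_two
#' @param chains number of chains; chain c uses a seed derived from `seed`.
#' @param ... passed to [run_stage_two()].
#' @return list of `melded_draws`, class `melded_chains`.
#' @export
run_stage_two_chains <- function(side1, side3, middle, pooled, chains = 4,
                                 seed = 1, ...) {
  out <- lapply(seq_len(chains), function(cc)
    run_stage_two(side1, side3, middle, pooled,
                  seed = derive_seed(seed, 100 + cc), ...))
  class(out) <- "melded_chains"
  out
}

#' Stack draws from multiple chains
#' @param chains a `melded_chains` object (or list of `melded_draws`).
#' @return single matrix of draws.
#' @export
combine_chains <- function(chains) {
  do.call(rbind, lapply(chains, `[[`, "draws"))
}
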