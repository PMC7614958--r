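---
title: "Chained Markov melding: models, samplers, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chained Markov melding: models, samplers, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainmeld)
```

## The problem

Applied Bayesian analyses often have several heterogeneous data sets, each
with a natural submodel, and no obvious joint model. When the submodels form
a *chain* — submodel $m$ shares a quantity $\phi_{m \cap m+1}$ with submodel
$m+1$ and nothing with any other submodel — they can be joined into a single
coherent joint model by *chained Markov melding*. Writing
$\phi = (\phi_{1\cap 2}, \dots, \phi_{M-1 \cap M})$ for the concatenation of
all shared quantities, $\psi_m$ for submodel-specific parameters, and $Y_m$
for submodel-specific data, the melded model is

$$
p_{\text{meld}}(\phi, \psi, Y) \;=\;
p_{\text{pool}}(\phi) \prod_{m=1}^{M}
\frac{p_m(\phi_m, \psi_m, Y_m)}{p_m(\phi_m)},
$$

i.e. each submodel has its own prior marginal over its shared quantities
*replaced* by a single pooled prior $p_{\text{pool}}(\phi)$, and the modified
submodels are then multiplied together (the Markov combination). Marginal
replacement is the KL-minimal modification of a submodel subject to its
shared-quantity marginal matching the pooled prior, so the construction is
conservative: it changes each submodel as little as possible.

`chainmeld` implements, for $M = 3$ chains (the case covering the bundled
examples), the four pooling operators, the melded-density assembly, a
two-stage parallel Metropolis-within-Gibbs sampler, a normal-approximation
variant, and a worked integrated population model (IPM) with a simulator.

## Pooled priors

The pooled prior must reconcile the submodels' possibly different prior
marginals for the same shared quantity, and decide how much of a middle
submodel's prior *correlation between* $\phi_{1\cap2}$ and $\phi_{2\cap3}$
survives. All operators work in log space and may return unnormalised
densities — normalising constants cancel in every Metropolis ratio the
package computes. A trapezoid-quadrature normaliser (`grid_normalise`) is
provided for one- and two-dimensional diagnostics only.

* **Logarithmic** (`pool_log`): $\prod_m p_m(\phi_m)^{\lambda_m}$. Retains
  middle-prior correlation. All weights equal to 1 is product-of-experts
  (PoE) pooling. The weight-sum condition $\sum_m \lambda_m \ge 1$ is
  checked with a warning, not an error: whether it is needed for propriety
  depends on tail behaviour the package cannot verify for arbitrary
  log-density callbacks.
* **Linear** (`pool_linear`): per overlap, a two-component mixture of the two
  flanking marginals; the pooled prior is the product of these mixtures, so
  distinct overlaps are *independent* by construction. Weights are indexed
  per overlap pair $(\lambda_{m,1}, \lambda_{m,2})$, the operative form; any
  required marginalisation of a bivariate middle prior is the caller's
  responsibility, either in closed form or via `marginalise_component`
  (1-D quadrature on declared support — never kernel density estimation,
  which is unreliable for the mixed discrete/continuous marginals this
  framework must eventually face).
* **Partial dictatorial** (`pool_dictatorial_partial`): one submodel's joint
  prior over its shared quantities is kept verbatim; remaining overlaps are
  pooled logarithmically or linearly per side. The admissible argument sets
  for the side operators are not restricted: for each side overlap the two
  flanking marginals are pooled, which reduces to the natural convention in
  the $M=3$ case (both sides vacuous).
* **Complete dictatorial** (`pool_dictatorial_complete`): each overlap is
  assigned to one of its two submodels; consecutive overlaps assigned to the
  same middle submodel keep that submodel's joint prior, preserving its
  dependence.

For Gaussian marginals, `gaussian_pool_closed_form` gives the exact
logarithmically pooled Gaussian by weighted precision addition; a sweep over
the middle weight shows that it controls the pooled correlation
monotonically, which the test suite checks.

```{r pooling-demo}
dc1 <- density_component(function(x) dnorm(x, -2.5, 1, log = TRUE), "phi12")
S2 <- matrix(c(1, 0.8, 0.8, 1), 2); P2 <- solve(S2)
dc2 <- density_component(function(x) -log(2*pi) - 0.5*log(det(S2)) -
                           0.5*drop(x %*% P2 %*% x), c("phi12", "phi23"))
dc3 <- density_component(function(x) dnorm(x, 2.5, 1, log = TRUE), "phi23")
poe <- pool_log(list(dc1, dc2, dc3), c(1, 1, 1))
g <- grid_normalise(pool_grid(poe, rbind(c(-6, 6), c(-6, 6)), n = 61))
grid_moments(g)$cor   # middle-prior correlation, attenuated by the sides
```

## The two-stage sampler

The sampler assumes the decomposition
$p_{\text{pool}}(\phi) = p_{\text{pool},1}(\phi_{1\cap2})\,
p_{\text{pool},2}(\phi)\, p_{\text{pool},3}(\phi_{2\cap3})$, which always
holds with flat side factors, and holds with the end submodels' own priors
as sides after adjusting the middle factor (`decompose_pooled`). The
subprior-sides choice makes the stage-one targets the ordinary
subposteriors, so existing per-submodel fits (or closed-form samplers, as
for the IPM fecundity submodel) can be reused unchanged.

**Stage one** samples $(\phi_{1\cap2}, \psi_1)$ and $(\phi_{2\cap3},
\psi_3)$ independently, in parallel if desired. **Stage two** runs
Metropolis-within-Gibbs on the full melded posterior with three blocks per
sweep, in fixed order (side 1, side 3, $\psi_2$; a random scan is available
behind a flag): the side blocks propose a uniformly drawn *index* into the
stage-one draws — with replacement; ties between equal rows need no
tie-breaking since their ratios are identical — and accept with a ratio
involving only the middle submodel and the middle pooled factor. Accepted
indices are stored and used to reattach $\psi_1, \psi_3$ verbatim, so the
side idiosyncratic parameters are never re-evaluated in stage two.

Numerical choices:

* The default $\psi_2$ kernel is a componentwise Gaussian random walk whose
  global step adapts (Robbins–Monro, target 0.44 for scalar / 0.234 for
  multivariate) during warmup only and is frozen afterwards, preserving the
  stationary distribution. Structured problems supply their own kernel
  (the IPM uses single-site discrete moves for the latent counts).
* Stage-two warmup defaults to 10% of sweeps, discarded. Split-$\hat R$,
  effective sample size (Geyer initial positive sequence), and Monte-Carlo
  standard errors are computed on retained sweeps.
* One root seed drives everything: stage-one side streams and stage-two
  chain streams are derived deterministically, so stages can be re-run
  independently and whole experiments are byte-reproducible.
* A fully rejected block over a long window raises a mixing *warning*, not
  an error; degenerate single-row stage-one pools are permitted (the side
  state is then constant, the remaining blocks still sample correctly).

Stage-one draws are proposed with replacement across the stage-two run; the
alternative without replacement would make the chain non-Markovian without
a clear benefit at the pool sizes used here.

A known limitation, visible in the Gaussian demonstration chain: when the
middle data strongly constrain a shared quantity, the conditional slab is
narrow relative to the stage-one pool and index proposals are often
rejected. Thinning the stage-one chains (supported directly) and
moderately informative middle data keep acceptance rates workable; the
bundled demonstration chain therefore gives the middle submodel weaker data
than the sides, which is also the configuration melding is for — the
bridging submodel is typically the weakly informed link.

## Normal-approximation melding

When the side subposteriors and side priors over the overlaps are
approximately Gaussian, the two side ratios collapse into one corrected
Gaussian factor with
$\hat\Sigma = (\hat\Sigma_{nu}^{-1} - \hat\Sigma_{de}^{-1})^{-1}$ and
$\hat\mu = \hat\Sigma(\hat\Sigma_{nu}^{-1}\hat\mu_{nu} -
\hat\Sigma_{de}^{-1}\hat\mu_{de})$, multiplying the middle submodel's
posterior kernel (its own bivariate prior kept — complete dictatorial
pooling with the middle authoritative). Under PoE pooling the denominator
terms vanish and the numerator is used unchanged. Design choices: the
Gaussian fit is moment matching (the conventional reading of "normal
approximation of draws" in multi-stage practice), with a Laplace-at-mode
option; the precision difference must be positive definite to an eigenvalue
floor of `1e-10`, and failures are fatal because the approximation is
meaningless otherwise. The side idiosyncratic parameters are integrated out
by assumption and are simply not reported by this route.

## The little-owls IPM

The worked example joins three submodels for a female owl population
observed over $T$ years:

1. **Capture-recapture** ($p_1$): released owls of age class $a \in \{J,
   A\}$ and sex $s$ are recaptured (or never seen again) with
   multinomial cell probabilities built from survival $\delta_{a,s,t}$ and
   recapture $\pi_{s,u}$ probabilities. An owl's survival keeps its
   release-cohort age class throughout, following the cell-probability
   product as specified; under the linear predictor below $\delta$ is
   constant in time anyway, but the `recapture_cell_probs` machinery stays
   general.
2. **Census counts** ($p_2$): observed female counts are Poisson around a
   latent population of juveniles (Poisson around
   $x_{t-1}\,(\rho/2)\,\delta_{J,F}$ — half of fledglings are assumed
   female), surviving adults (binomial) and immigrants (Poisson with rate
   $\eta$); an extinct population propagates point masses at zero.
3. **Fecundity** ($p_3$): fledgling counts are Poisson with mean
   $N_t \rho$.

Linear predictors: $\mathrm{logit}(\delta_{a,s,t}) = \alpha_0 + \alpha_1
I(s{=}M) + \alpha_2 I(a{=}A)$, $\mathrm{logit}(\pi_{s,u}) = \alpha_4
I(s{=}M) + \alpha_{5,u}$ (the yearly $\alpha_{5,u}$ shared across sexes,
with the male offset $\alpha_4$), $\log \eta_t = \alpha_6$. Priors:
Normal$(0, 2^2)$ truncated to $[-10, 10]$ on every coefficient,
Uniform$(0, 10)$ on $\rho$, discrete uniform $\{0,\dots,50\}$ on the initial
populations. The shared quantities are $\phi_{1\cap2} = (\alpha_0,
\alpha_2)$ and $\phi_{2\cap3} = \rho$. Because the submodels place
*identical* priors on the shared quantities, logarithmic pooling with
weights $(1/2, 1/2, 1/2)$ (and equal-weight linear pooling) reproduces those
priors exactly and the melded model *is* the monolithic joint IPM — the
package exploits this to benchmark the two-stage sampler against direct
MCMC on the joint model. PoE pooling squares the truncated-normal prior for
$(\alpha_0, \alpha_2)$, visibly concentrating it around zero.

The latent integer states are updated by single-site discrete random-walk
moves ($\pm1, \pm2$) inside the $\psi_2$ block; marginalising them is not
attempted. Survival probabilities are stored per $(a, s, t)$ even though
constant in $t$, keeping the recapture machinery reusable.

### What the simulator emulates

`simulate_ipm` draws data from exactly the likelihoods above: the latent
population trajectory, Poisson census counts, multinomial recapture tables
for a fixed number of releases per stratum-year, and Poisson fledgling
counts with the breeding-female count set to the realised female
population. Defaults (chosen once as field-realistic values for a small owl
population): juvenile female survival 0.30, adult 0.50, a modest male
deficit ($\alpha_1 = -0.3$), recapture probability about 0.62 for females,
immigration rate 0.20/year, fecundity 2.6 fledglings per breeding female,
initial populations 15 juveniles and 20 adults. These give a slowly growing
population (roughly 9%/year), so count magnitudes stay in a realistic range
over the default $T = 15$ years. What the simulator does *not* emulate:
individual heterogeneity in survival or detection, tag loss, observation
error in the nest-record data, and temporal variation in survival or
immigration — passing tests therefore validate the estimation machinery
under the model, not robustness to model misspecification in real owl data.

Test-scale choices: simulations use $T = 15$ with about 50 releases per
stratum-year and stage-two runs of a few thousand sweeps; parameter-recovery
checks use 10 replicate simulations. These sizes give interval estimates
whose Monte-Carlo error is well below the posterior spread while keeping the
full suite quick on a single CPU.

```{r ipm-demo}
data <- simulate_ipm(ipm_true_state(12), T = 12, releases = 40, seed = 1)
fit <- fit_ipm_meld(data, pooling = "logarithmic", n_stage1 = 800,
                    sweeps = 800, chains = 1, seed = 1,
                    stage1_warmup = 2000, stage1_thin = 2)
summarise_intervals(fit$draws, levels = c(0.5, 0.95),
                    params = c("alpha0", "alpha2", "rho"))
unlist(data$truth[c("alpha0", "alpha2", "rho")])
```

## Degenerate inputs and tie-breaks

* Density components return $-\infty$ outside declared support; a positive
  count on a structural zero of the recapture table yields a $-\infty$
  log-likelihood, not an exception.
* A pooled prior evaluated where a submodel prior marginal vanishes raises a
  support-mismatch error during marginal replacement: silently continuing
  would hide an inconsistent pooling choice. This is conservative — a
  mismatch on a measure-zero set is treated the same way.
* All-zero pooling weights, negative weights, zero-sum mixture pairs, and
  out-of-range dictatorial selections are hard errors.
* Quantiles everywhere use type-7 linear interpolation (R's default),
  stated here because interval tables are part of the package's output
  contract.

## Known limitations

* Chains longer than $M = 3$ are supported for pooling and melded-density
  evaluation, but the two-stage sampler and its decomposition triple target
  the three-submodel case.
* Copula-based dependent linear pooling, mixed discrete/continuous
  marginals, and weight elicitation are out of scope.
* The index-recycling proposals confine stage two to the stage-one support;
  pathological stage-one pools (too short, unconverged) bias the melded
  posterior, which is why stage-one thinning and diagnostics are exposed
  rather than hidden.
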