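# Pooling operators for chained melding.
#
# A chain of M submodels shares phi_{m (intersect) m+1} between neighbours m and
# m+1 only.  The pooled prior p_pool(phi) over the concatenation of all overlap
# quantities is built from the submodel prior marginals p_m(phi_m) by one of
# four operators: logarithmic, linear, partial dictatorial, complete
# dictatorial.  Everything is handled in log space and may be unnormalised;
# normalisation constants cancel in the Metropolis acceptance ratios, so an
# explicit quadrature normaliser is provided for <= 2-D diagnostics only.

#' Declare a prior density component over shared quantities
#'
#' A density component holds the log-density of one submodel's prior marginal
#' over a declared subset of the shared-quantity vector.
#'
#' @param log_density function taking a numeric vector of length
#'   `length(vars)` (the coordinates named in `vars`, in that order) and
#'   returning a scalar log-density.  Need not be normalised unless
#'   `proper = TRUE` is meant literally.
#' @param vars character vector naming the shared coordinates this component
#'   covers.
#' @param support optional list, one entry per coordinate: either a numeric
#'   `c(lo, hi)` interval or a [discrete_set()] of allowed values.  The
#'   evaluator returns `-Inf` outside the support.  Default: unbounded.
#' @param proper logical flag: does the component integrate to 1 over its
#'   declared support?
#' @return an object of class `density_component`.
#' @export
density_component <- function(log_density, vars, support = NULL, proper = TRUE) {
  stopifnot(is.function(log_density), is.character(vars), length(vars) >= 1)
  if (!is.null(support)) {
    stopifnot(is.list(support), length(support) == length(vars))
  }
  structure(
    list(log_density = log_density, vars = vars, support = support,
         proper = isTRUE(proper)),
    class = "density_component"
  )
}

#' Discrete support set for a coordinate
#' @param values numeric vector of allowed values.
#' @export
discrete_set <- function(values) structure(list(values = values), class = "discrete_set")

in_support <- function(dc, x) {
  if (is.null(dc$support)) return(TRUE)
  for (i in seq_along(x)) {
    s <- dc$support[[i]]
    if (inherits(s, "discrete_set")) {
      if (!x[i] %in% s$values) return(FALSE)
    } else if (x[i] < s[1] || x[i] > s[2]) {
      return(FALSE)
    }
  }
  TRUE
}

#' Evaluate a density component at a point of the full shared vector
#'
#' @param dc a [density_component()].
#' @param phi named numeric vector containing (at least) the coordinates in
#'   `dc$vars`.
#' @return scalar log-density; `-Inf` outside the declared support.
#' @export
dc_eval <- function(dc, phi) {
  x <- phi[dc$vars]
  if (anyNA(x)) stop("missing coordinates: ", paste(dc$vars[is.na(x)], collapse = ", "))
  if (!in_support(dc, x)) return(-Inf)
  dc$log_density(unname(x))
}

flat_component <- function(vars) {
  density_component(function(x) 0, vars = vars, proper = FALSE)
}

new_pooled_prior <- function(log_density, vars, overlap_vars, factors, method,
                             weights = NULL, normalised = FALSE) {
  structure(
    list(log_density = log_density, vars = vars, overlap_vars = overlap_vars,
         factors = factors, method = method, weights = weights,
         normalised = normalised),
    class = "pooled_prior"
  )
}

#' @export
print.pooled_prior <- function(x, ...) {
  cat("Pooled prior (", x$method, ") over: ", paste(x$vars, collapse = ", "),
      "\n", sep = "")
  flat <- vapply(x$factors, function(f) isTRUE(f$flat), logical(1))
  cat("Decomposition factors:",
      paste(names(x$factors), ifelse(flat, "[flat]", ""), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the joint pooled log-density
#' @param pooled a `pooled_prior`.
#' @param phi named numeric vector over the pooled coordinates.
#' @return scalar log-density (unnormalised unless stated).
#' @export
pooled_eval <- function(pooled, phi) pooled$log_density(phi)

#' Evaluate one factor of the three-way pooled-prior decomposition
#' @param pooled a `pooled_prior`.
#' @param which one of "left", "middle", "right".
#' @param phi named numeric vector.
#' @export
pooled_factor_eval <- function(pooled, which, phi) {
  f <- pooled$factors[[which]]
  if (is.null(f)) stop("no such factor: ", which)
  dc_eval(f$component, phi)
}

default_factors <- function(joint_dc, overlap_vars) {
  K <- length(overlap_vars)
  list(
    left   = list(component = flat_component(overlap_vars[[1]]), flat = TRUE),
    middle = list(component = joint_dc, flat = FALSE),
    right  = list(component = flat_component(overlap_vars[[K]]), flat = TRUE)
  )
}

check_weights <- function(weights, n, what = "weights") {
  if (length(weights) != n)
    stop("invalid-weights: expected ", n, " ", what, ", got ", length(weights))
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("invalid-weights: pooling weights must be finite and nonnegative")
  invisible(weights)
}

overlap_vars_from_marginals <- function(marginals) {
  M <- length(marginals)
  lapply(seq_len(M - 1), function(m) {
    ov <- intersect(marginals[[m]]$vars, marginals[[m + 1]]$vars)
    if (length(ov) == 0)
      stop("submodels ", m, " and ", m + 1, " share no coordinates")
    ov
  })
}

#' Chained logarithmic pooling
#'
#' Forms `log p_pool(phi) = sum_m lambda_m log p_m(phi_m)` (up to a constant).
#' With all weights equal to 1 this is product-of-experts (PoE) pooling.
#' Unlike linear pooling, any prior correlation between the two overlap
#' quantities inside a middle submodel's marginal is retained.
#'
#' @param marginals list of [density_component()]s, one per submodel, each over
#'   that submodel's shared quantities `phi_m` (adjacent components must share
#'   at least one coordinate).
#' @param weights nonnegative numeric vector, one weight per submodel.  A
#'   warning is emitted when `sum(weights) < 1`, since propriety of the pooled
#'   prior is then not guaranteed in general.
#' @return a `pooled_prior` (flat-sides decomposition by default; see
#'   [decompose_pooled()]).
#' @export
pool_log <- function(marginals, weights) {
  M <- length(marginals)
  check_weights(weights, M)
  if (all(weights == 0))
    stop("degenerate-pooling: all logarithmic pooling weights are zero")
  if (sum(weights) < 1)
    warning("sum of logarithmic pooling weights < 1; pooled prior may be improper")
  vars <- unique(unlist(lapply(marginals, `[[`, "vars")))
  ov <- overlap_vars_from_marginals(marginals)
  active <- which(weights > 0)
  f <- function(phi) {
    tot <- 0
    for (m in active) {
      lm <- dc_eval(marginals[[m]], phi)
      if (lm == -Inf) return(-Inf)
      tot <- tot + weights[m] * lm
    }
    tot
  }
  joint_dc <- density_component(function(x) f(stats::setNames(x, vars)),
                                vars = vars, proper = FALSE)
  new_pooled_prior(f, vars, ov, default_factors(joint_dc, ov),
                   method = "logarithmic", weights = weights)
}

#' Chained linear pooling
#'
#' Two-step procedure: for each overlap `m (intersect) m+1`, the two submodel
#' marginals of that quantity are combined by standard linear (mixture)
#' pooling; the pooled prior is then the product of these per-overlap
#' intermediaries, so distinct overlap quantities are independent under the
#' result.
#'
#' @param adjacent_marginals list with one element per overlap; each element is
#'   a list of two [density_component()]s over the same overlap coordinates:
#'   the marginal of submodel m and of submodel m+1 (any required
#'   marginalisation of a middle submodel's bivariate prior must already have
#'   been applied, e.g. via [marginalise_component()]).
#' @param weights list (or (M-1) x 2 matrix) of nonnegative weight pairs
#'   `(lambda_{m,1}, lambda_{m,2})`, one pair per overlap.
#' @return a `pooled_prior`; its decomposition puts the first intermediary in
#'   the left factor and the last in the right factor (flat middle) when there
#'   are exactly two overlaps.
#' @export
pool_linear <- function(adjacent_marginals, weights) {
  K <- length(adjacent_marginals)
  if (is.matrix(weights)) weights <- lapply(seq_len(nrow(weights)), function(i) weights[i, ])
  stopifnot(length(weights) == K)
  intermediaries <- vector("list", K)
  ov <- vector("list", K)
  for (k in seq_len(K)) {
    pair <- adjacent_marginals[[k]]
    stopifnot(length(pair) == 2)
    if (!identical(pair[[1]]$vars, pair[[2]]$vars))
      stop("overlap ", k, ": the two marginals cover different coordinates")
    w <- check_weights(weights[[k]], 2, "weights for one overlap")
    if (sum(w) == 0)
      stop("degenerate-mixture: weight pair for overlap ", k, " sums to zero")
    ov[[k]] <- pair[[1]]$vars
    intermediaries[[k]] <- local({
      p <- pair; lw <- log(w); vk <- pair[[1]]$vars
      act <- which(w > 0)
      density_component(function(x) {
        phi <- stats::setNames(x, vk)
        logsumexp(vapply(act, function(i) lw[i] + dc_eval(p[[i]], phi), 0))
      }, vars = vk, proper = FALSE)
    })
  }
  vars <- unique(unlist(ov))
  f <- function(phi) {
    tot <- 0
    for (k in seq_len(K)) {
      lk <- dc_eval(intermediaries[[k]], phi)
      if (lk == -Inf) return(-Inf)
      tot <- tot + lk
    }
    tot
  }
  factors <- if (K == 2) {
    list(left   = list(component = intermediaries[[1]], flat = FALSE),
         middle = list(component = flat_component(unlist(ov)), flat = TRUE),
         right  = list(component = intermediaries[[2]], flat = FALSE))
  } else {
    joint_dc <- density_component(function(x) f(stats::setNames(x, vars)),
                                  vars = vars, proper = FALSE)
    default_factors(joint_dc, ov)
  }
  new_pooled_prior(f, vars, ov, factors, method = "linear", weights = weights)
}

#' Prior set for a chain of submodels (dictatorial pooling input)
#'
#' @param joints list of M [density_component()]s: submodel m's prior over its
#'   own shared quantities `phi_m`.
#' @param overlap_vars list of M-1 character vectors: the coordinates of each
#'   overlap `phi_{m (intersect) m+1}`.
#' @param marginals optional list of M named lists; `marginals[[m]][[as.character(k)]]`
#'   is submodel m's marginal over overlap k, needed when a middle submodel's
#'   prior must be marginalised to a single overlap (see
#'   [marginalise_component()]).
#' @export
chain_prior_set <- function(joints, overlap_vars, marginals = NULL) {
  M <- length(joints)
  stopifnot(length(overlap_vars) == M - 1)
  structure(list(joints = joints, overlap_vars = overlap_vars,
                 marginals = marginals %||% rep(list(list()), M), M = M),
            class = "chain_prior_set")
}

# Fetch submodel m's marginal over overlap k, falling back to the joint when
# the joint already covers exactly that overlap (end submodels).
chain_marginal <- function(cp, m, k) {
  ovk <- cp$overlap_vars[[k]]
  j <- cp$joints[[m]]
  if (identical(sort(j$vars), sort(ovk))) return(j)
  mk <- cp$marginals[[m]][[as.character(k)]]
  if (is.null(mk))
    stop("need submodel ", m, "'s marginal over overlap ", k,
         "; supply it in chain_prior_set(marginals=) or use marginalise_component()")
  mk
}

#' Marginalise a two-coordinate density component by 1-D quadrature
#'
#' Integrates out one coordinate of a bivariate component over its declared
#' (finite) interval support, returning the marginal of the kept coordinate.
#' Intended for building the per-overlap marginals that linear and complete
#' dictatorial pooling require when a middle submodel's prior is not supplied
#' in closed form.  No kernel density estimation is used anywhere.
#'
#' @param dc a bivariate [density_component()] with finite interval support on
#'   the integrated coordinate.
#' @param keep name of the coordinate to keep.
#' @param n number of quadrature nodes (trapezoid rule).
#' @return a univariate `density_component` (normalised like `dc` is).
#' @export
marginalise_component <- function(dc, keep, n = 1001) {
  stopifnot(length(dc$vars) == 2, keep %in% dc$vars)
  drop_i <- which(dc$vars != keep)
  keep_i <- which(dc$vars == keep)
  s <- dc$support[[drop_i]]
  if (is.null(s) || inherits(s, "discrete_set") || any(!is.finite(s)))
    stop("marginalise_component needs finite interval support on the integrated coordinate")
  nodes <- seq(s[1], s[2], length.out = n)
  w <- rep((s[2] - s[1]) / (n - 1), n); w[c(1, n)] <- w[1] / 2
  lw <- log(w)
  keep_support <- if (is.null(dc$support)) NULL else dc$support[keep_i]
  density_component(function(x) {
    z <- numeric(2)
    z[keep_i] <- x
    lv <- vapply(nodes, function(u) { z[drop_i] <- u; dc$log_density(z) }, 0)
    logsumexp(lv + lw)
  }, vars = keep, support = keep_support, proper = dc$proper)
}

#' Partial dictatorial pooling
#'
#' Designates submodel `authoritative`'s prior over its own shared quantities
#' as the middle factor of the pooled prior, verbatim; the remaining overlap
#' quantities to its left and right are pooled by a standard operator
#' (logarithmic or linear) per side.  With M = 3 and `authoritative = 2` both
#' sides are vacuous and the pooled prior is exactly the middle submodel's
#' bivariate prior.
#'
#' @param chain_priors a [chain_prior_set()].
#' @param authoritative index m of the authoritative submodel.
#' @param side_modes length-2 character vector, pooling operator for the left
#'   and right side: "logarithmic" or "linear".
#' @param side_weights optional list with elements `left` and `right` giving
#'   weights for the side operators (defaults: all 1 for logarithmic, equal
#'   pairs for linear).
#' @return a `pooled_prior`.
#' @export
pool_dictatorial_partial <- function(chain_priors, authoritative,
                                     side_modes = c("logarithmic", "logarithmic"),
                                     side_weights = NULL) {
  cp <- chain_priors
  M <- cp$M
  m <- authoritative
  if (!(is.numeric(m) && length(m) == 1 && m >= 1 && m <= M))
    stop("authoritative index out of range: ", m)
  K <- M - 1
  mid_dc <- cp$joints[[m]]
  # overlaps owned by the authoritative submodel
  own <- intersect(c(m - 1, m), seq_len(K))
  left_ov <- seq_len(K)[seq_len(K) < min(own)]
  right_ov <- seq_len(K)[seq_len(K) > max(own)]
  side_pool <- function(ovs, mode, wts) {
    if (length(ovs) == 0) return(NULL)
    pairs <- lapply(ovs, function(k)
      list(chain_marginal(cp, k, k), chain_marginal(cp, k + 1, k)))
    if (mode == "linear") {
      pool_linear(pairs, wts %||% rep(list(c(0.5, 0.5)), length(ovs)))
    } else {
      # logarithmic over the two flanking marginals of each overlap
      comps <- unlist(pairs, recursive = FALSE)
      pool_log(comps, wts %||% rep(1, length(comps)))
    }
  }
  g1 <- side_pool(left_ov, match.arg(side_modes[1], c("logarithmic", "linear")),
                  side_weights$left)
  g2 <- side_pool(right_ov, match.arg(side_modes[2], c("logarithmic", "linear")),
                  side_weights$right)
  vars <- unique(unlist(cp$overlap_vars))
  f <- function(phi) {
    tot <- dc_eval(mid_dc, phi)
    if (!is.null(g1)) tot <- tot + g1$log_density(phi)
    if (!is.null(g2)) tot <- tot + g2$log_density(phi)
    tot
  }
  factors <- if (M == 3 && m == 2) {
    list(left   = list(component = flat_component(cp$overlap_vars[[1]]), flat = TRUE),
         middle = list(component = mid_dc, flat = FALSE),
         right  = list(component = flat_component(cp$overlap_vars[[2]]), flat = TRUE))
  } else {
    joint_dc <- density_component(function(x) f(stats::setNames(x, vars)),
                                  vars = vars, proper = FALSE)
    default_factors(joint_dc, cp$overlap_vars)
  }
  new_pooled_prior(f, vars, cp$overlap_vars, factors, method = "partial-dictatorial")
}

#' Complete dictatorial pooling
#'
#' For each overlap `m (intersect) m+1` one of the two submodels holding it is
#' selected as authoritative; the pooled prior is the product of the selected
#' marginals.  When two consecutive overlaps are both assigned to the same
#' (middle) submodel, that submodel's joint prior over the two overlaps is
#' used instead, retaining its prior dependence.
#'
#' @param chain_priors a [chain_prior_set()].
#' @param selections integer vector of length M-1; `selections[k]` must be `k`
#'   or `k + 1`.
#' @return a `pooled_prior`.
#' @export
pool_dictatorial_complete <- function(chain_priors, selections) {
  cp <- chain_priors
  K <- cp$M - 1
  stopifnot(length(selections) == K)
  for (k in seq_len(K)) {
    if (!selections[k] %in% c(k, k + 1))
      stop("selection for overlap ", k, " must be ", k, " or ", k + 1,
           "; got ", selections[k])
  }
  terms <- list()
  k <- 1
  while (k <= K) {
    s <- selections[k]
    if (k < K && selections[k + 1] == s) {
      # submodel s = k+1 owns both overlaps k and k+1: keep its joint prior
      terms[[length(terms) + 1]] <- list(component = cp$joints[[s]], overlaps = c(k, k + 1))
      k <- k + 2
    } else {
      terms[[length(terms) + 1]] <- list(component = chain_marginal(cp, s, k), overlaps = k)
      k <- k + 1
    }
  }
  vars <- unique(unlist(cp$overlap_vars))
  f <- function(phi) {
    tot <- 0
    for (tm in terms) {
      lt <- dc_eval(tm$component, phi)
      if (lt == -Inf) return(-Inf)
      tot <- tot + lt
    }
    tot
  }
  factors <- if (K == 2) {
    if (length(terms) == 1) {
      list(left   = list(component = flat_component(cp$overlap_vars[[1]]), flat = TRUE),
           middle = list(component = terms[[1]]$component, flat = FALSE),
           right  = list(component = flat_component(cp$overlap_vars[[2]]), flat = TRUE))
    } else {
      list(left   = list(component = terms[[1]]$component, flat = FALSE),
           middle = list(component = flat_component(vars), flat = TRUE),
           right  = list(component = terms[[2]]$component, flat = FALSE))
    }
  } else {
    joint_dc <- density_component(function(x) f(stats::setNames(x, vars)),
                                  vars = vars, proper = FALSE)
    default_factors(joint_dc, cp$overlap_vars)
  }
  new_pooled_prior(f, vars, cp$overlap_vars, factors, method = "complete-dictatorial")
}

#' Re-decompose a pooled prior for the two-stage sampler
#'
#' The parallel sampler assumes `p_pool(phi) = p_pool,1(phi_{1^2})
#' p_pool,2(phi) p_pool,3(phi_{2^3})`.  Every pooled prior satisfies this
#' trivially with flat (improper) side factors; alternatively the side factors
#' can be set to the end submodels' own priors, which makes the stage-one
#' targets the ordinary subposteriors.
#'
#' @param pooled a `pooled_prior` over exactly two overlaps.
#' @param mode `"flat-sides"` (side factors constant) or `"subprior-sides"`.
#' @param side_priors for `"subprior-sides"`: list of two
#'   [density_component()]s over the left and right overlap, strictly positive
#'   wherever the pooled prior is.
#' @return the same pooled prior with a new decomposition triple; the three
#'   factors always sum (in log space) to the joint pooled log-density.
#' @export
decompose_pooled <- function(pooled, mode = c("flat-sides", "subprior-sides"),
                             side_priors = NULL) {
  mode <- match.arg(mode)
  K <- length(pooled$overlap_vars)
  if (K != 2) stop("decomposition triple is defined for chains with two overlaps (M = 3)")
  lv <- pooled$overlap_vars[[1]]
  rv <- pooled$overlap_vars[[2]]
  if (mode == "flat-sides") {
    joint_dc <- density_component(
      function(x) pooled$log_density(stats::setNames(x, pooled$vars)),
      vars = pooled$vars, proper = FALSE)
    factors <- list(left = list(component = flat_component(lv), flat = TRUE),
                    middle = list(component = joint_dc, flat = FALSE),
                    right = list(component = flat_component(rv), flat = TRUE))
  } else {
    stopifnot(length(side_priors) == 2)
    lp <- side_priors[[1]]; rp <- side_priors[[2]]
    if (!identical(sort(lp$vars), sort(lv)) || !identical(sort(rp$vars), sort(rv)))
      stop("side priors must cover the left and right overlap coordinates")
    mid <- density_component(function(x) {
      phi <- stats::setNames(x, pooled$vars)
      lj <- pooled$log_density(phi)
      if (lj == -Inf) return(-Inf)
      ll <- dc_eval(lp, phi); lr <- dc_eval(rp, phi)
      if (ll == -Inf || lr == -Inf)
        stop("division-by-zero: side prior is zero where the pooled prior is positive")
      lj - ll - lr
    }, vars = pooled$vars, proper = FALSE)
    factors <- list(left = list(component = lp, flat = FALSE),
                    middle = list(component = mid, flat = FALSE),
                    right = list(component = rp, flat = FALSE))
  }
  pooled$factors <- factors
  pooled
}

#' Closed-form logarithmic pooling of Gaussian components
#'
#' Logarithmic pooling of (possibly multivariate) normal prior marginals is
#' again normal: precisions embed into the full shared-coordinate space, are
#' weighted and added.  The middle weight controls how much of the middle
#' submodel's prior correlation between the two overlaps survives pooling.
#'
#' @param components list of Gaussian components, each a list with elements
#'   `mean`, `cov` and `vars` (coordinate names), e.g. a [gaussian_summary()].
#' @param weights nonnegative numeric vector, one per component.
#' @return a [gaussian_summary()] over the union of coordinates.
#' @export
gaussian_pool_closed_form <- function(components, weights) {
  M <- length(components)
  check_weights(weights, M)
  vars <- unique(unlist(lapply(components, `[[`, "vars")))
  d <- length(vars)
  P <- matrix(0, d, d, dimnames = list(vars, vars))
  b <- stats::setNames(numeric(d), vars)
  for (m in seq_len(M)) {
    if (weights[m] == 0) next
    cm <- components[[m]]
    idx <- match(cm$vars, vars)
    Pm <- solve(cm$cov)
    P[idx, idx] <- P[idx, idx] + weights[m] * Pm
    b[idx] <- b[idx] + weights[m] * drop(Pm %*% cm$mean)
  }
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12)
    stop("improper-pooled-prior: pooled precision is not positive definite ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  cov <- solve(P)
  cov <- (cov + t(cov)) / 2
  gaussian_summary(drop(cov %*% b), cov, vars = vars)
}

# ---- grid diagnostics (<= 2-D) ----------------------------------------------

#' Tabulate a pooled prior on a regular grid
#'
#' @param pooled a `pooled_prior` (or any object with `$log_density` and
#'   `$vars`) over one or two coordinates.
#' @param limits matrix with one row per coordinate and columns `c(lo, hi)`.
#' @param n grid points per axis (default 201).
#' @return data frame with one coordinate column per variable plus
#'   `log_density`.
#' @export
pool_grid <- function(pooled, limits, n = 201) {
  vars <- pooled$vars
  d <- length(vars)
  if (d > 2) stop("grid diagnostics support at most two coordinates")
  limits <- matrix(limits, nrow = d)
  axes <- lapply(seq_len(d), function(i) seq(limits[i, 1], limits[i, 2], length.out = n))
  grid <- do.call(expand.grid, stats::setNames(axes, vars))
  ld <- apply(as.matrix(grid), 1, function(x) pooled$log_density(stats::setNames(x, vars)))
  grid$log_density <- ld
  attr(grid, "vars") <- vars
  grid
}

grid_weights <- function(ax) {
  n <- length(ax)
  w <- rep(diff(ax)[1], n)
  w[c(1, n)] <- w[1] / 2
  w
}

#' Normalise a gridded log-density by trapezoid quadrature
#'
#' @param grid output of [pool_grid()].
#' @return the grid with a `density` column integrating to ~1, plus the log
#'   normalising constant as attribute `log_const`.
#' @export
grid_normalise <- function(grid) {
  vars <- attr(grid, "vars")
  w <- rep(1, nrow(grid))
  for (v in vars) {
    ax <- sort(unique(grid[[v]]))
    w <- w * grid_weights(ax)[match(grid[[v]], ax)]
  }
  lZ <- logsumexp(grid$log_density + log(w))
  grid$density <- exp(grid$log_density - lZ)
  attr(grid, "log_const") <- lZ
  grid
}

#' Moments of a gridded (normalised) density
#'
#' @param grid output of [grid_normalise()].
#' @return list with `mean`, `cov` and (for 2-D) `cor`.
#' @export
grid_moments <- function(grid) {
  vars <- attr(grid, "vars")
  w <- rep(1, nrow(grid))
  for (v in vars) {
    ax <- sort(unique(grid[[v]]))
    w <- w * grid_weights(ax)[match(grid[[v]], ax)]
  }
  p <- grid$density * w
  p <- p / sum(p)
  X <- as.matrix(grid[vars])
  mu <- colSums(X * p)
  ctr <- sweep(X, 2L, mu)
  cv <- t(ctr) %*% (ctr * p)
  out <- list(mean = mu, cov = cv)
  if (length(vars) == 2) out$cor <- cv[1, 2] / sqrt(cv[1, 1] * cv[2, 2])
  out
}
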