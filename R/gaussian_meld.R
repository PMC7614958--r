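# Normal-approximation melding.
#
# The side subposteriors and side priors over the overlap quantities are
# summarised as Gaussians; the ratio (subposterior / prior) for both sides
# collapses, via standard Gaussian density algebra, into a single corrected
# Gaussian factor that multiplies the middle submodel's posterior kernel.
# Requires the middle submodel's own bivariate prior to be kept (complete
# dictatorial pooling with the middle submodel authoritative for both
# overlaps), and integrates psi_1, psi_3 out of the reported posterior.

#' Gaussian summary of a shared quantity
#'
#' @param mean numeric mean vector.
#' @param cov covariance matrix; symmetry is enforced to 1e-12 and positive
#'   definiteness checked.
#' @param vars optional coordinate labels tying the summary to shared-quantity
#'   slots.
#' @return object of class `gaussian_summary`.
#' @export
gaussian_summary <- function(mean, cov, vars = NULL) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  d <- length(mean)
  stopifnot(nrow(cov) == d, ncol(cov) == d)
  if (max(abs(cov - t(cov))) > 1e-12 * max(1, max(abs(cov))))
    stop("covariance matrix is not symmetric")
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("rank-deficiency error: covariance not positive definite (min eigenvalue ",
         format(min(ev)), ")")
  if (is.null(vars)) vars <- paste0("x", seq_len(d))
  structure(list(mean = stats::setNames(mean, vars), cov = cov, vars = vars),
            class = "gaussian_summary")
}

#' @export
print.gaussian_summary <- function(x, ...) {
  cat("Gaussian summary over:", paste(x$vars, collapse = ", "), "\n")
  cat("mean:", signif(x$mean, 4), "\n")
  cat("cov:\n"); print(signif(x$cov, 4))
  invisible(x)
}

#' Moment-matched Gaussian fit
#'
#' Fits a Gaussian to draws by matching the sample mean and covariance, or
#' passes an analytic Gaussian through unchanged.
#'
#' @param x matrix of draws (rows = draws) or a `gaussian_summary`.
#' @param vars optional coordinate labels.
#' @return a [gaussian_summary()].
#' @export
fit_gaussian <- function(x, vars = NULL) {
  if (inherits(x, "gaussian_summary")) return(x)
  x <- as.matrix(x)
  d <- ncol(x)
  if (nrow(x) < d + 1)
    stop("need at least d + 1 = ", d + 1, " draws to fit a ", d, "-D Gaussian")
  cv <- stats::cov(x)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(1, max(ev)))
    stop("rank-deficiency error: sample covariance is singular")
  gaussian_summary(colMeans(x), cv, vars = vars %||% colnames(x))
}

#' Laplace (mode + curvature) Gaussian fit
#'
#' Alternative to moment matching: locates the mode of a log-density by
#' quasi-Newton optimisation and uses the negative inverse Hessian (central
#' finite differences) as covariance.
#'
#' @param log_density function of a numeric vector.
#' @param init starting point.
#' @param vars optional coordinate labels.
#' @param h finite-difference step.
#' @return a [gaussian_summary()].
#' @export
fit_gaussian_laplace <- function(log_density, init, vars = NULL, h = 1e-4) {
  opt <- stats::optim(init, function(x) -log_density(x), method = "BFGS")
  mode <- opt$par
  d <- length(mode)
  H <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(i)) {
    ei <- ej <- numeric(d); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (log_density(mode + ei + ej) - log_density(mode + ei - ej) -
         log_density(mode - ei + ej) + log_density(mode - ei - ej)) / (4 * h^2)
  }
  gaussian_summary(mode, solve(-H), vars = vars)
}

#' Stack two Gaussian summaries block-diagonally
#'
#' @param a,b [gaussian_summary()]s over disjoint coordinate sets.
#' @return a [gaussian_summary()] over the concatenated coordinates.
#' @export
gaussian_block_diag <- function(a, b) {
  da <- length(a$mean); db <- length(b$mean)
  cv <- matrix(0, da + db, da + db)
  cv[seq_len(da), seq_len(da)] <- a$cov
  cv[da + seq_len(db), da + seq_len(db)] <- b$cov
  gaussian_summary(c(a$mean, b$mean), cv, vars = c(a$vars, b$vars))
}

#' Gaussian ratio correction for approximate melding
#'
#' Computes the Gaussian whose density is proportional to the ratio of the
#' numerator Gaussian density (side subposteriors, stacked block-diagonally)
#' to the denominator Gaussian density (side priors):
#' `Sigma = (Sigma_nu^-1 - Sigma_de^-1)^-1`,
#' `mu = Sigma (Sigma_nu^-1 mu_nu - Sigma_de^-1 mu_de)`.
#' Under product-of-experts pooling the denominator terms are absent and the
#' numerator is returned unchanged.
#'
#' @param numerator a [gaussian_summary()] (e.g. from
#'   [gaussian_block_diag()]).
#' @param denominator a [gaussian_summary()] over the same coordinates, or
#'   `NULL` for the PoE branch.
#' @param eig_floor smallest admissible eigenvalue of the precision
#'   difference.
#' @return a [gaussian_summary()].
#' @export
gaussian_correction <- function(numerator, denominator = NULL,
                                eig_floor = 1e-10) {
  if (is.null(denominator)) return(numerator)
  stopifnot(length(numerator$mean) == length(denominator$mean))
  P_nu <- solve(numerator$cov)
  P_de <- solve(denominator$cov)
  P <- P_nu - P_de
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < eig_floor)
    stop("improper-correction error: precision difference not positive ",
         "definite (smallest eigenvalue ", format(min(ev)), "); the side ",
         "subposterior must be tighter than the side prior in every direction")
  cov <- solve(P)
  cov <- (cov + t(cov)) / 2
  mu <- drop(cov %*% (P_nu %*% numerator$mean - P_de %*% denominator$mean))
  gaussian_summary(mu, cov, vars = numerator$vars)
}

#' Approximate melded log-density
#'
#' `log p_hat_meld(phi, psi_2 | Y) = log N(phi; mu_hat, Sigma_hat) +
#'  log p_2(phi, psi_2, Y_2)` (the middle submodel keeps its own prior for
#' phi, per the dictatorial-middle pooling assumption).
#'
#' @param correction a [gaussian_summary()] over the full overlap vector, as
#'   from [gaussian_correction()].
#' @param middle the middle [submodel_spec()].
#' @return function `(phi, psi2)` (phi a named vector over both overlaps)
#'   returning the log-density, suitable for [mh_sample()].
#' @export
approx_melded_log_density <- function(correction, middle) {
  vars <- correction$vars
  if (!setequal(vars, middle$phi_vars))
    stop("correction coordinates do not match the middle submodel's shared slots")
  function(phi, psi2 = numeric(0)) {
    if (length(phi) != length(vars)) stop("dimension mismatch in phi")
    lg <- dmvnorm_log(unname(phi[vars]), correction$mean, correction$cov)
    lj <- middle$log_joint(phi, psi2)
    if (lj == -Inf) return(-Inf)
    lg + lj
  }
}
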