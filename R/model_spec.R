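# Chain-of-submodels representation and the chained melded model.
#
# Submodel m has data Y_m, shared quantities phi_m (its left and/or right
# overlap with neighbours) and idiosyncratic parameters psi_m.  Marginal
# replacement swaps each submodel's own prior marginal over phi_m for the
# pooled prior; the Markov combination of the replaced submodels is the
# chained melded model:
#   p_meld(phi, psi, Y) = p_pool(phi) * prod_m p_m(phi_m, psi_m, Y_m) / p_m(phi_m)

# Normalise a slot declaration (named dims or plain character) to coordinates.
slot_coords <- function(slots) {
  if (is.null(slots) || length(slots) == 0) return(character(0))
  if (is.character(slots)) return(slots)
  stopifnot(!is.null(names(slots)))
  unlist(lapply(names(slots), function(nm) {
    d <- slots[[nm]]
    if (d == 1) nm else paste0(nm, "[", seq_len(d), "]")
  }), use.names = FALSE)
}

#' Declare one submodel of a chain
#'
#' @param name label used in diagnostics.
#' @param log_joint function `(phi, psi)` returning the submodel log joint
#'   density `log p_m(phi_m, psi_m, Y_m)` (data baked in).  `phi` is a named
#'   numeric vector over this submodel's shared coordinates, `psi` a numeric
#'   vector of idiosyncratic parameters (length 0 allowed).
#' @param log_phi_marginal function of the named shared vector `phi_m`
#'   returning the submodel's analytic prior marginal `log p_m(phi_m)`.  The
#'   package never estimates this from draws.
#' @param phi_left,phi_right shared-quantity slots with the left/right
#'   neighbour: a character vector of coordinate names, or a named vector of
#'   slot dimensions (dimension d expands to `name[1] ... name[d]`).
#' @param psi_names optional character vector naming the psi components.
#' @param sampler optional direct subposterior sampler: function `(n, seed)`
#'   returning a matrix with `length(phi)+length(psi)` columns (phi columns
#'   first) of draws from `p_m(phi_m, psi_m | Y_m)`.
#' @param psi_init optional numeric vector: initial psi for MCMC.
#' @param phi_init optional named numeric vector: initial phi for MCMC.
#' @return an object of class `submodel_spec`.
#' @export
submodel_spec <- function(name, log_joint, log_phi_marginal,
                          phi_left = NULL, phi_right = NULL,
                          psi_names = character(0), sampler = NULL,
                          psi_init = NULL, phi_init = NULL) {
  left <- slot_coords(phi_left)
  right <- slot_coords(phi_right)
  if (length(left) == 0 && length(right) == 0)
    stop("submodel '", name, "' declares no shared quantities")
  if (anyDuplicated(c(left, right)))
    stop("submodel '", name, "': left and right slots overlap")
  structure(
    list(name = name, log_joint = log_joint,
         log_phi_marginal = log_phi_marginal,
         phi_left = left, phi_right = right,
         phi_vars = c(left, right), psi_names = psi_names,
         sampler = sampler, psi_init = psi_init, phi_init = phi_init),
    class = "submodel_spec"
  )
}

#' Validate the structure of a chain of submodels
#'
#' Checks adjacency (submodel m's right slot must equal submodel m+1's left
#' slot, names and dimensions), that end submodels have no outward slots, and
#' that no coordinate name is reused across non-adjacent overlaps.
#'
#' @param submodels list of [submodel_spec()]s in chain order.
#' @return character vector of issues (empty when well formed).
#' @export
validate_chain <- function(submodels) {
  M <- length(submodels)
  issues <- character(0)
  if (M < 3) issues <- c(issues, sprintf("chain has %d submodels; need M >= 3", M))
  if (length(submodels) >= 1 && length(submodels[[1]]$phi_left) > 0)
    issues <- c(issues, "first submodel declares a left overlap (no left neighbour)")
  if (M >= 1 && length(submodels[[M]]$phi_right) > 0)
    issues <- c(issues, "last submodel declares a right overlap (no right neighbour)")
  for (m in seq_len(max(M - 1, 0))) {
    r <- submodels[[m]]$phi_right
    l <- submodels[[m + 1]]$phi_left
    if (!identical(r, l)) {
      issues <- c(issues, sprintf(
        "overlap %d: submodel %d right slot (%s; dim %d) != submodel %d left slot (%s; dim %d)",
        m, m, paste(r, collapse = ","), length(r),
        m + 1, paste(l, collapse = ","), length(l)))
    }
  }
  if (M >= 2) {
    ov <- lapply(seq_len(M - 1), function(m) submodels[[m]]$phi_right)
    all_coords <- unlist(ov)
    if (anyDuplicated(all_coords)) {
      dup <- unique(all_coords[duplicated(all_coords)])
      issues <- c(issues, sprintf(
        "coordinate(s) %s appear in more than one overlap (non-adjacent sharing)",
        paste(dup, collapse = ",")))
    }
  }
  issues
}

#' Assemble a chain model
#'
#' @param submodels list of M >= 3 [submodel_spec()]s in chain order.
#' @return object of class `chain_model` with the canonical concatenated
#'   shared-vector layout.
#' @export
chain_model <- function(submodels) {
  issues <- validate_chain(submodels)
  if (length(issues) > 0)
    stop("invalid chain:\n  ", paste(issues, collapse = "\n  "))
  M <- length(submodels)
  overlap_vars <- lapply(seq_len(M - 1), function(m) submodels[[m]]$phi_right)
  phi_layout <- unlist(overlap_vars, use.names = FALSE)
  structure(
    list(submodels = submodels, M = M, overlap_vars = overlap_vars,
         phi_layout = phi_layout),
    class = "chain_model"
  )
}

#' @export
print.chain_model <- function(x, ...) {
  cat("Chain of", x$M, "submodels:",
      paste(vapply(x$submodels, `[[`, "", "name"), collapse = " -- "), "\n")
  cat("Shared layout:", paste(x$phi_layout, collapse = ", "), "\n")
  invisible(x)
}

#' Marginal replacement of one submodel
#'
#' Returns the log-density of the marginally replaced submodel,
#' `log p_repl,m = log p_pool(phi) + log p_m(phi_m, psi_m, Y_m) - log p_m(phi_m)`,
#' the KL-minimal modification of `p_m` whose shared-quantity marginal is the
#' pooled prior's.
#'
#' @param sub a [submodel_spec()].
#' @param pooled a `pooled_prior` over the full shared vector.
#' @return function `(phi, psi)` (phi named over the full shared vector).
#' @export
marginal_replace <- function(sub, pooled) {
  force(sub); force(pooled)
  function(phi, psi = numeric(0)) {
    lp <- pooled$log_density(phi)
    if (lp == -Inf) return(-Inf)
    phim <- phi[sub$phi_vars]
    lm <- sub$log_phi_marginal(phim)
    if (lm == -Inf)
      stop("support-mismatch: p_", sub$name,
           "(phi_m) is zero at a point with positive pooled prior mass")
    lp + sub$log_joint(phim, psi) - lm
  }
}

#' Build the chained melded model
#'
#' @param chain a [chain_model()].
#' @param pooled a `pooled_prior` whose coordinates match the chain layout.
#' @return object of class `melded_model`.
#' @export
melded_model <- function(chain, pooled) {
  if (!setequal(pooled$vars, chain$phi_layout))
    stop("pooled prior coordinates (", paste(pooled$vars, collapse = ","),
         ") do not match the chain layout (",
         paste(chain$phi_layout, collapse = ","), ")")
  structure(list(chain = chain, pooled = pooled), class = "melded_model")
}

#' Evaluate the chained melded log-density
#'
#' `log p_meld(phi, psi, Y) = log p_pool(phi) +
#'  sum_m [ log p_m(phi_m, psi_m, Y_m) - log p_m(phi_m) ]`.
#'
#' @param model a [melded_model()].
#' @param phi named numeric vector over the full shared layout.
#' @param psi list of M numeric vectors (idiosyncratic parameters per
#'   submodel; use `numeric(0)` where empty).
#' @return scalar log-density.
#' @export
melded_log_density <- function(model, phi, psi) {
  chain <- model$chain
  if (length(psi) != chain$M)
    stop("psi must be a list of length M = ", chain$M)
  if (!setequal(names(phi), chain$phi_layout))
    stop("phi names do not match the chain layout")
  tot <- model$pooled$log_density(phi)
  if (tot == -Inf) return(-Inf)
  for (m in seq_len(chain$M)) {
    sub <- chain$submodels[[m]]
    phim <- phi[sub$phi_vars]
    lj <- sub$log_joint(phim, psi[[m]])
    if (lj == -Inf) return(-Inf)
    lm <- sub$log_phi_marginal(phim)
    tot <- tot + lj - lm
  }
  tot
}
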