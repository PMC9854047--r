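#' Spike-and-slab prior on the band coefficients
#'
#' Each coefficient has prior
#' `p(beta_j | gamma_j) = (1 - gamma_j) I(beta_j = 0) + gamma_j N(mu_j, nu_j)`
#' with `P(gamma_j = 0) = p0_j`.  Scalars are recycled over the `p` bands.
#' The slab defaults (`mu = 0`, `nu = 1`) are calibrated for predictors
#' standardized to unit variance, which [fit_model()] does internally.  The
#' default exclusion probability `p0 = 0.9` encodes a prior expected model
#' size of about 10% of the bands: with more candidate bands than plots and
#' strong between-band collinearity, an indifferent `p0 = 0.5` admits
#' enough spurious bands to visibly absorb residual variance, whereas
#' nutrient signal is carried by a small subset of wavelengths.
#'
#' @param p0 prior probability that a coefficient is excluded, in (0, 1).
#' @param mu slab mean(s).
#' @param nu slab variance(s), > 0.
#' @return A `spike_slab_prior` list.
#' @export
spike_slab_prior <- function(p0 = 0.9, mu = 0, nu = 1) {
  stopifnot(all(p0 > 0), all(p0 < 1), all(nu > 0))
  structure(list(p0 = p0, mu = mu, nu = nu), class = "spike_slab_prior")
}

#' Inverse-gamma prior for a variance component
#'
#' `IG(alpha, eta)` with density proportional to
#' `x^{-(alpha+1)} exp(-eta / x)` (shape/rate).  The default
#' `alpha = eta = 0.01` is weakly informative.
#'
#' @param alpha shape, > 0.
#' @param eta rate, > 0.
#' @return A `variance_prior` list.
#' @export
variance_prior <- function(alpha = 0.01, eta = 0.01) {
  stopifnot(alpha > 0, eta > 0)
  structure(list(alpha = alpha, eta = eta), class = "variance_prior")
}

#' Uniform prior for the spatial dependence parameter
#'
#' For the geostatistical model the support is `(0, 1)` (decay rate per
#' metre); for the CAR model it is the eigenvalue-derived open interval
#' `(1/lambda_(1), 1/lambda_(n))` of the field structure.
#'
#' @param lo,hi support bounds, `lo < hi`.
#' @return A `phi_prior` list.
#' @export
phi_prior <- function(lo = 0, hi = 1) {
  stopifnot(lo < hi)
  structure(list(lo = lo, hi = hi), class = "phi_prior")
}

#' Default prior bundle for a model kind
#'
#' @param kind `"independent"`, `"geospatial"`, or `"car"`.
#' @param fs `field_structure`, required for `"car"` (phi support).
#' @param p number of band coefficients (for recycling checks only).
#' @return List with elements `beta` ([spike_slab_prior()]), `sigma2`,
#'   `tau2` ([variance_prior()]) and `phi` ([phi_prior()]) as applicable.
#' @export
default_priors <- function(kind = c("independent", "geospatial", "car"),
                           fs = NULL, p = NULL) {
  kind <- match.arg(kind)
  pr <- list(beta = spike_slab_prior())
  if (kind == "independent") {
    pr$sigma2 <- variance_prior()
  } else if (kind == "geospatial") {
    pr$sigma2 <- variance_prior()
    pr$tau2 <- variance_prior()
    pr$phi <- phi_prior(0, 1)
  } else {
    if (is.null(fs)) stop("CAR priors need a field_structure for phi support")
    pr$tau2 <- variance_prior()
    pr$phi <- phi_prior(fs$phi_support[1], fs$phi_support[2])
  }
  pr
}

#' MCMC configuration
#'
#' @param n_iter total iterations.
#' @param burn_in iterations discarded (< `n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed RNG seed (integer); the whole chain is a deterministic
#'   function of it.
#' @param phi_proposal_sd random-walk scale for the Metropolis-Hastings phi
#'   update, on the logit-transformed scale; adapted during burn-in toward a
#'   20--50% acceptance rate and frozen afterwards.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 10000, burn_in = 5000, thin = 5,
                        seed = 1, phi_proposal_sd = 0.25) {
  stopifnot(burn_in < n_iter, thin >= 1, phi_proposal_sd >= 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 phi_proposal_sd = phi_proposal_sd),
            class = "mcmc_config")
}
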