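# --- Gibbs / Metropolis-Hastings full-conditional updates -------------------
#
# The sampler state is a plain list:
#   kind       one of "independent", "geospatial", "car"
#   beta       band coefficients (length p)
#   gamma      inclusion indicators (length p, 0/1)
#   intercept  scalar, always included, never subject to selection
#   sigma2     residual variance (model 1) / spatial-field variance (model 2)
#   tau2       nugget variance (model 2) / CAR conditional variance (model 3)
#   phi        spatial dependence parameter (models 2, 3)
#   w          latent spatial field (model 2)
# `data` is a list (or regression_dataset) with elements y and X.
# These R functions are thin, test-friendly surfaces over the same kernels
# the main sampler in fit_model() uses.

new_state <- function(kind, y, X, fs = NULL) {
  p <- ncol(X)
  st <- list(kind = kind, beta = rep(0, p), gamma = rep(1L, p),
             intercept = 0, sigma2 = var(y), tau2 = var(y),
             phi = NA_real_, w = rep(0, length(y)))
  if (kind == "geospatial") st$phi <- 0.5
  if (kind == "car") st$phi <- mean(fs$phi_support)
  st
}

# Error-precision-weighted design V = P X for the sweep kernel.
sweep_inputs <- function(state, y, Xa, fs) {
  if (state$kind == "independent") {
    list(ystar = y, V = Xa / state$sigma2)
  } else if (state$kind == "geospatial") {
    list(ystar = y - state$w, V = Xa / state$tau2)
  } else {
    list(ystar = y,
         V = (fs$d_m * Xa - state$phi * (fs$M %*% Xa)) / state$tau2)
  }
}

#' Spike-and-slab update of the coefficients and inclusion indicators
#'
#' One Gibbs sweep, in random coordinate order, over the intercept and all
#' band coefficients.  For each band `j`, `gamma_j` is drawn from its
#' Bernoulli full conditional (the slab-vs-spike Bayes factor with `beta_j`
#' integrated out), then `beta_j` from its conjugate normal if included,
#' else set exactly to 0.  The intercept always takes the normal draw.
#'
#' @param state sampler state list (see [fit_model()] internals).
#' @param data list with `y` and `X`.
#' @param prior a [spike_slab_prior()].
#' @param fs `field_structure` (required for the CAR kind).
#' @return The updated state.
#' @export
update_beta_gamma <- function(state, data, prior, fs = NULL) {
  y <- data$y; X <- data$X
  p <- ncol(X)
  Xa <- cbind(1, X)
  si <- sweep_inputs(state, y, Xa, fs)
  b <- c(state$intercept, state$beta)
  g <- c(1L, state$gamma)
  r <- si$ystar - drop(Xa %*% b)
  res <- sweep_beta_gamma_cpp(
    Xa, si$V, r, b, g,
    p0 = c(0.5, rep_len(prior$p0, p)),
    mu = c(0, rep_len(prior$mu, p)),
    nu = c(1e6, rep_len(prior$nu, p)),
    force_in = c(TRUE, rep(FALSE, p)),
    order = sample.int(p + 1L))
  state$intercept <- res$beta[1]
  state$beta <- res$beta[-1]
  state$gamma <- res$gamma[-1]
  state
}

rinvgamma1 <- function(shape, rate) 1 / rgamma(1L, shape = shape, rate = rate)

#' Inverse-gamma update of the variance components
#'
#' Draws each variance from its conjugate inverse-gamma full conditional:
#' shape `alpha + n/2`, rate `eta + 0.5 * (residual quadratic form)`.  For
#' the CAR model the quadratic form is `r' (D_M - phi M) r`; for the
#' geostatistical model `sigma2` (the field variance) uses `w' H(phi)^{-1} w`
#' and `tau2` (the nugget) the plain residual sum of squares.
#'
#' @param state sampler state.
#' @param data list with `y` and `X`.
#' @param prior list of [variance_prior()]s, elements `sigma2` and/or `tau2`.
#' @param fs `field_structure` (CAR) or `NULL`.
#' @param Hinv optional precomputed `H(phi)^{-1}` (geostatistical).
#' @return The updated state.
#' @export
update_variances <- function(state, data, prior, fs = NULL, Hinv = NULL) {
  y <- data$y; X <- data$X
  n <- length(y)
  mu <- state$intercept + drop(X %*% state$beta)
  if (state$kind == "independent") {
    r <- y - mu
    state$sigma2 <- rinvgamma1(prior$sigma2$alpha + n / 2,
                               prior$sigma2$eta + 0.5 * sum(r^2))
  } else if (state$kind == "geospatial") {
    r <- y - mu - state$w
    state$tau2 <- rinvgamma1(prior$tau2$alpha + n / 2,
                             prior$tau2$eta + 0.5 * sum(r^2))
    if (is.null(Hinv)) {
      H <- exp_correlation(distance_matrix(fs), state$phi)
      Hinv <- chol2inv(chol(H))
    }
    qf <- drop(crossprod(state$w, Hinv %*% state$w))
    state$sigma2 <- rinvgamma1(prior$sigma2$alpha + n / 2,
                               prior$sigma2$eta + 0.5 * qf)
  } else {
    r <- y - mu
    state$tau2 <- rinvgamma1(prior$tau2$alpha + n / 2,
                             prior$tau2$eta + 0.5 * car_quad(fs, state$phi, r))
  }
  state
}

# Logit transform of phi onto the real line and back, with log-Jacobian of
# the inverse map (needed for detailed balance of the random walk).
phi_to_z <- function(phi, lo, hi) {
  u <- (phi - lo) / (hi - lo)
  log(u) - log1p(-u)
}
z_to_phi <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)
log_jacobian_z <- function(z, lo, hi) {
  # d phi / d z = (hi - lo) u (1 - u) with u = plogis(z)
  log(hi - lo) + stats::plogis(z, log.p = TRUE) +
    stats::plogis(-z, log.p = TRUE)
}

#' Metropolis-Hastings update of the spatial dependence parameter
#'
#' Gaussian random walk on the logit transform of `(phi - lo)/(hi - lo)`,
#' with Jacobian-corrected acceptance ratio.  The phi-dependent target is
#' the latent-field prior density for the geostatistical model and the
#' joint CAR likelihood for the CAR model.  With `proposal_sd = 0` the
#' chain stays at its current value.
#'
#' @param state sampler state.
#' @param data list with `y` and `X`.
#' @param fs `field_structure`.
#' @param prior a [phi_prior()].
#' @param proposal_sd random-walk scale on the transformed scale.
#' @param log_target optional custom log-density of phi (overrides the
#'   model-specific default; used in tests).
#' @return The updated state, with `state$phi_accepted` (0/1) recorded.
#' @export
update_phi_mh <- function(state, data, fs, prior, proposal_sd = 0.25,
                          log_target = NULL) {
  lo <- prior$lo; hi <- prior$hi
  if (is.null(log_target)) {
    if (state$kind == "geospatial") {
      D <- distance_matrix(fs)
      w <- state$w; s2 <- state$sigma2
      log_target <- function(phi) {
        R <- chol(exp_correlation(D, max(phi, .Machine$double.eps)))
        v <- backsolve(R, w, transpose = TRUE)
        -sum(log(diag(R))) - sum(v^2) / (2 * s2)
      }
    } else if (state$kind == "car") {
      r <- data$y - state$intercept - drop(data$X %*% state$beta)
      tau2 <- state$tau2
      log_target <- function(phi)
        0.5 * car_logdet(fs, phi) - car_quad(fs, phi, r) / (2 * tau2)
    } else stop("phi update undefined for the independent model")
  }
  z <- phi_to_z(state$phi, lo, hi)
  zprop <- z + proposal_sd * rnorm(1L)
  phiprop <- z_to_phi(zprop, lo, hi)
  logr <- (log_target(phiprop) + log_jacobian_z(zprop, lo, hi)) -
    (log_target(state$phi) + log_jacobian_z(z, lo, hi))
  acc <- is.finite(logr) && log(runif(1L)) < logr
  if (acc) state$phi <- phiprop
  state$phi_accepted <- as.integer(acc)
  state
}

#' Gibbs update of the latent spatial field (geostatistical model)
#'
#' Draws `w` from its multivariate normal full conditional with precision
#' `H(phi)^{-1}/sigma2 + I/tau2` and mean solving that precision against
#' `(y - X beta - intercept)/tau2`, via Cholesky factorizations (no
#' explicit inverses beyond `chol2inv` of a triangular factor).
#'
#' @param state sampler state (`kind == "geospatial"`).
#' @param data list with `y` and `X`.
#' @param fs `field_structure` (plot coordinates).
#' @param Hinv optional precomputed `H(phi)^{-1}`.
#' @return The updated state.
#' @export
update_w <- function(state, data, fs, Hinv = NULL) {
  stopifnot(state$kind == "geospatial")
  y <- data$y; X <- data$X
  n <- length(y)
  if (is.null(Hinv)) {
    H <- exp_correlation(distance_matrix(fs), state$phi)
    R <- chol(H)
    dg <- diag(R)
    if (max(dg) / min(dg) > 1e8)
      stop("correlation matrix ill-conditioned: condition number of chol ",
           "factor ~ ", format((max(dg) / min(dg))^2, digits = 3))
    Hinv <- chol2inv(R)
  }
  A <- Hinv / state$sigma2 + diag(n) / state$tau2
  RA <- chol(A)
  rhs <- (y - state$intercept - drop(X %*% state$beta)) / state$tau2
  m <- backsolve(RA, backsolve(RA, rhs, transpose = TRUE))
  state$w <- m + backsolve(RA, rnorm(n))
  state
}
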