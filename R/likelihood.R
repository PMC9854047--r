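# CAR log-determinant and quadratic form, both without forming an inverse.
# With L = D_M^{-1/2} M D_M^{-1/2} and eigenvalues lambda,
#   log det(D_M - phi M) = sum(log d_m) + sum(log(1 - phi * lambda)).
car_logdet <- function(fs, phi) {
  sum(log(fs$d_m)) + sum(log1p(-phi * fs$lambda))
}

car_quad <- function(fs, phi, r) {
  sum(fs$d_m * r^2) - phi * drop(crossprod(r, fs$M %*% r))
}

#' Model log-likelihood
#'
#' Evaluates the log sampling density of `y` for one of the three model
#' kinds at a full set of parameter values:
#' * `"independent"`: `sum log N(y_i | mu_i, sigma2)`;
#' * `"geospatial"` (conditional on the spatial field `w`):
#'   `sum log N(y_i | mu_i + w_i, tau2)`;
#' * `"car"`: the joint `log N(y | mu, tau2 (D_M - phi M)^{-1})`, evaluated
#'   through the eigenvalue factorization of the scaled adjacency (no
#'   explicit inverse).
#'
#' Here `mu = intercept + X beta` (or just `intercept` when `X` is `NULL`).
#'
#' @param kind `"independent"`, `"geospatial"`, or `"car"`.
#' @param y response vector.
#' @param X design matrix (bands), or `NULL` for an intercept-only mean.
#' @param params list with the model's parameters among `beta`, `intercept`
#'   (default 0), `sigma2`, `tau2`, `phi`, `w`.
#' @param fs `field_structure`, required for `"car"`.
#' @return The log-density (scalar).
#' @export
loglik <- function(kind = c("independent", "geospatial", "car"),
                   y, X = NULL, params = list(), fs = NULL) {
  kind <- match.arg(kind)
  n <- length(y)
  intercept <- if (is.null(params$intercept)) 0 else params$intercept
  mu <- rep(intercept, n)
  if (!is.null(X) && !is.null(params$beta)) mu <- mu + drop(X %*% params$beta)
  if (kind == "independent") {
    stopifnot(params$sigma2 > 0)
    sum(dnorm(y, mu, sqrt(params$sigma2), log = TRUE))
  } else if (kind == "geospatial") {
    stopifnot(params$tau2 > 0, length(params$w) == n)
    sum(dnorm(y, mu + params$w, sqrt(params$tau2), log = TRUE))
  } else {
    if (is.null(fs)) stop("CAR likelihood needs a field_structure")
    stopifnot(params$tau2 > 0)
    if (params$phi <= fs$phi_support[1] || params$phi >= fs$phi_support[2])
      stop("phi outside support: CAR precision not positive definite")
    r <- y - mu
    -n / 2 * log(2 * pi * params$tau2) + 0.5 * car_logdet(fs, params$phi) -
      car_quad(fs, params$phi, r) / (2 * params$tau2)
  }
}
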