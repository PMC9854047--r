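#' Fit a spike-and-slab band-selection model by MCMC
#'
#' Runs the Gibbs sampler (with a Metropolis-Hastings step for the spatial
#' dependence parameter) for one of the three model kinds:
#'
#' * `"independent"`: `y = intercept + X beta + eps`, `eps ~ N(0, sigma2 I)`;
#' * `"geospatial"`: adds a latent field `w ~ N(0, sigma2 H(phi))` with
#'   exponential correlogram `H(phi) = exp(-phi d_ij)` and nugget
#'   `eps ~ N(0, tau2 I)`;
#' * `"car"`: joint `y ~ N(intercept + X beta, tau2 (D_M - phi M)^{-1})` on
#'   the field adjacency graph.
#'
#' Each coefficient carries a spike-and-slab prior inducing band selection;
#' the intercept is always included and never selected over.  Predictors are
#' standardized internally (mean 0, unit variance) and coefficient draws are
#' returned on the original scale.  The per-iteration sweep order is
#' coefficients (random order), variance components, phi, then the latent
#' field; the phi proposal scale is adapted during burn-in toward a 20--50%
#' acceptance rate and frozen afterwards.  The chain is a deterministic
#' function of `cfg$seed`.
#'
#' The stored per-draw deviance (the DIC focus) is the model's likelihood of
#' `y` alone: for the geospatial kind the latent field is integrated out
#' (`y ~ N(X beta, sigma2 H(phi) + tau2 I)`), so DIC compares all three
#' kinds on marginal likelihoods of the same data.
#'
#' @param y response vector (log grain phosphorus).
#' @param X n x p band matrix.
#' @param kind `"independent"`, `"geospatial"`, or `"car"`.
#' @param fs `field_structure`; required for the two spatial kinds.
#' @param priors list as from [default_priors()]; `NULL` for defaults.
#' @param cfg an [mcmc_config()].
#' @param standardize standardize the columns of `X` internally (default).
#' @param selection if `FALSE`, all bands are forced into the model (used
#'   when refitting on a pre-selected band set).
#' @param keep_w store the latent-field draws (geospatial only).
#' @return A `posterior_samples` object: thinned draws of `beta` (original
#'   scale), `intercept`, `gamma`, the variance components, `phi`, `w`, the
#'   per-draw `deviance`, the deviance at the posterior means
#'   (`deviance_at_mean`), posterior means (`post_mean`), the phi acceptance
#'   rate, and the configuration.
#' @export
fit_model <- function(y, X, kind = c("independent", "geospatial", "car"),
                      fs = NULL, priors = NULL, cfg = mcmc_config(),
                      standardize = TRUE, selection = TRUE, keep_w = TRUE) {
  kind <- match.arg(kind)
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n)
  if (kind != "independent" && is.null(fs))
    stop("the ", kind, " model needs a field_structure")
  if (!is.null(fs) && fs$n != n)
    stop("field_structure has ", fs$n, " plots but y has ", n)
  if (is.null(priors)) priors <- default_priors(kind, fs = fs, p = p)

  set.seed(cfg$seed)

  # standardization (predictors only; intercept handled separately)
  if (standardize) {
    cm <- colMeans(X)
    csd <- apply(X, 2, sd)
    if (any(csd == 0)) stop("constant predictor column(s): ",
                            paste(which(csd == 0), collapse = ", "))
    Xs <- sweep(sweep(X, 2, cm), 2, csd, "/")
  } else {
    cm <- rep(0, p); csd <- rep(1, p); Xs <- X
  }
  Xa <- cbind(1, Xs)

  p0v <- c(0.5, rep_len(priors$beta$p0, p))
  muv <- c(0, rep_len(priors$beta$mu, p))
  nuv <- c(1e6, rep_len(priors$beta$nu, p))
  force_in <- c(TRUE, rep(!selection, p))

  b <- rep(0, p + 1)
  g <- as.integer(c(1L, rep(1L, p)))
  sigma2 <- var(y); tau2 <- var(y)
  phi <- NA_real_
  w <- rep(0, n)
  prop_sd <- cfg$phi_proposal_sd
  acc_window <- 0L; acc_total <- 0L; n_phi <- 0L

  # model-specific precomputations
  if (kind == "car") {
    phi_lo <- priors$phi$lo; phi_hi <- priors$phi$hi
    phi <- (phi_lo + phi_hi) / 2
    DXa <- fs$d_m * Xa
    MXa <- fs$M %*% Xa
  } else if (kind == "geospatial") {
    phi_lo <- priors$phi$lo; phi_hi <- priors$phi$hi
    phi <- (phi_lo + phi_hi) / 2
    Dmat <- distance_matrix(fs)
    Hcur <- exp_correlation(Dmat, phi)
    RH <- chol(Hcur)
    Hinv <- chol2inv(RH)
  }
  # marginal (w-integrated) gaussian deviance, used for the DIC focus of
  # the geospatial model: y ~ N(mu, sigma2 H + tau2 I)
  marg_dev <- function(yv, mu, H, s2, t2) {
    R <- chol(s2 * H + t2 * diag(n))
    v <- backsolve(R, yv - mu, transpose = TRUE)
    -2 * (-n / 2 * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(v^2))
  }

  n_keep <- floor((cfg$n_iter - cfg$burn_in) / cfg$thin)
  bn <- if (!is.null(colnames(X))) colnames(X) else paste0("b", seq_len(p))
  beta_dr <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, bn))
  gamma_dr <- matrix(NA_integer_, n_keep, p, dimnames = list(NULL, bn))
  int_dr <- numeric(n_keep)
  sigma2_dr <- if (kind != "car") numeric(n_keep) else NULL
  tau2_dr <- if (kind != "independent") numeric(n_keep) else NULL
  phi_dr <- if (kind != "independent") numeric(n_keep) else NULL
  w_dr <- if (kind == "geospatial" && keep_w)
    matrix(NA_real_, n_keep, n) else NULL
  dev_dr <- numeric(n_keep)
  # running sums (standardized scale) for posterior means / DIC plug-in
  sum_b <- numeric(p + 1); sum_s2 <- 0; sum_t2 <- 0; sum_phi <- 0
  sum_w <- numeric(n)

  kk <- 0L
  for (it in seq_len(cfg$n_iter)) {
    # --- beta / gamma sweep ---
    if (kind == "independent") {
      ystar <- y; V <- Xa / sigma2
    } else if (kind == "geospatial") {
      ystar <- y - w; V <- Xa / tau2
    } else {
      ystar <- y; V <- (DXa - phi * MXa) / tau2
    }
    r <- ystar - drop(Xa %*% b)
    sw <- sweep_beta_gamma_cpp(Xa, V, r, b, g, p0v, muv, nuv, force_in,
                               sample.int(p + 1L))
    b <- sw$beta; g <- sw$gamma; r <- sw$r

    # --- variance components ---
    if (kind == "independent") {
      sigma2 <- rinvgamma1(priors$sigma2$alpha + n / 2,
                           priors$sigma2$eta + 0.5 * sum(r^2))
    } else if (kind == "geospatial") {
      tau2 <- rinvgamma1(priors$tau2$alpha + n / 2,
                         priors$tau2$eta + 0.5 * sum(r^2))
      qfw <- drop(crossprod(w, Hinv %*% w))
      sigma2 <- rinvgamma1(priors$sigma2$alpha + n / 2,
                           priors$sigma2$eta + 0.5 * qfw)
    } else {
      qf <- sum(fs$d_m * r^2) - phi * drop(crossprod(r, fs$M %*% r))
      tau2 <- rinvgamma1(priors$tau2$alpha + n / 2,
                         priors$tau2$eta + 0.5 * qf)
    }

    # --- phi (Metropolis-Hastings on the logit scale) ---
    if (kind != "independent" && prop_sd >= 0) {
      z <- phi_to_z(phi, phi_lo, phi_hi)
      zp <- z + prop_sd * rnorm(1L)
      php <- z_to_phi(zp, phi_lo, phi_hi)
      if (kind == "car") {
        rMr <- drop(crossprod(r, fs$M %*% r))
        dr2 <- sum(fs$d_m * r^2)
        lt <- function(ph) 0.5 * car_logdet(fs, ph) -
          (dr2 - ph * rMr) / (2 * tau2)
        logr <- (lt(php) + log_jacobian_z(zp, phi_lo, phi_hi)) -
          (lt(phi) + log_jacobian_z(z, phi_lo, phi_hi))
        if (is.finite(logr) && log(runif(1L)) < logr) {
          phi <- php; acc_window <- acc_window + 1L; acc_total <- acc_total + 1L
        }
      } else {
        Hp <- exp_correlation(Dmat, php)
        RHp <- chol(Hp)
        vcur <- backsolve(RH, w, transpose = TRUE)
        vprop <- backsolve(RHp, w, transpose = TRUE)
        lt_cur <- -sum(log(diag(RH))) - sum(vcur^2) / (2 * sigma2)
        lt_prop <- -sum(log(diag(RHp))) - sum(vprop^2) / (2 * sigma2)
        logr <- (lt_prop + log_jacobian_z(zp, phi_lo, phi_hi)) -
          (lt_cur + log_jacobian_z(z, phi_lo, phi_hi))
        if (is.finite(logr) && log(runif(1L)) < logr) {
          phi <- php; Hcur <- Hp; RH <- RHp; Hinv <- chol2inv(RH)
          acc_window <- acc_window + 1L; acc_total <- acc_total + 1L
        }
      }
      n_phi <- n_phi + 1L
      # burn-in adaptation toward 20-50% acceptance, frozen afterwards
      if (it <= cfg$burn_in && it %% 50L == 0L && prop_sd > 0) {
        rate <- acc_window / 50
        if (rate < 0.2) prop_sd <- prop_sd * 0.8
        else if (rate > 0.5) prop_sd <- prop_sd * 1.25
        acc_window <- 0L
      }
    }

    # --- latent spatial field ---
    if (kind == "geospatial") {
      A <- Hinv / sigma2 + diag(n) / tau2
      RA <- chol(A)
      rhs <- (y - drop(Xa %*% b)) / tau2
      mw <- backsolve(RA, backsolve(RA, rhs, transpose = TRUE))
      w <- mw + backsolve(RA, rnorm(n))
    }

    # --- record ---
    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L) {
      kk <- kk + 1L
      bb <- b[-1] / csd
      int_dr[kk] <- b[1] - sum(b[-1] * cm / csd)
      beta_dr[kk, ] <- bb
      gamma_dr[kk, ] <- g[-1]
      mu_fit <- drop(Xa %*% b)
      if (kind == "independent") {
        sigma2_dr[kk] <- sigma2
        dev <- -2 * sum(dnorm(y, mu_fit, sqrt(sigma2), log = TRUE))
      } else if (kind == "geospatial") {
        sigma2_dr[kk] <- sigma2; tau2_dr[kk] <- tau2; phi_dr[kk] <- phi
        if (!is.null(w_dr)) w_dr[kk, ] <- w
        dev <- marg_dev(y, mu_fit, Hcur, sigma2, tau2)
      } else {
        tau2_dr[kk] <- tau2; phi_dr[kk] <- phi
        rr <- y - mu_fit
        dev <- -2 * (-n / 2 * log(2 * pi * tau2) +
                       0.5 * car_logdet(fs, phi) -
                       car_quad(fs, phi, rr) / (2 * tau2))
      }
      if (!is.finite(dev))
        stop("non-finite deviance at iteration ", it, " (divergent chain)")
      dev_dr[kk] <- dev
      sum_b <- sum_b + b; sum_s2 <- sum_s2 + sigma2; sum_t2 <- sum_t2 + tau2
      if (kind != "independent") sum_phi <- sum_phi + phi
      if (kind == "geospatial") sum_w <- sum_w + w
    }
  }

  # posterior means and plug-in deviance
  b_bar <- sum_b / n_keep
  beta_bar <- b_bar[-1] / csd
  int_bar <- b_bar[1] - sum(b_bar[-1] * cm / csd)
  s2_bar <- sum_s2 / n_keep; t2_bar <- sum_t2 / n_keep
  phi_bar <- if (kind != "independent") sum_phi / n_keep else NA_real_
  w_bar <- sum_w / n_keep
  mu_bar <- drop(Xa %*% b_bar)
  dev_at_mean <- if (kind == "independent") {
    -2 * sum(dnorm(y, mu_bar, sqrt(s2_bar), log = TRUE))
  } else if (kind == "geospatial") {
    marg_dev(y, mu_bar, exp_correlation(Dmat, phi_bar), s2_bar, t2_bar)
  } else {
    rr <- y - mu_bar
    -2 * (-n / 2 * log(2 * pi * t2_bar) + 0.5 * car_logdet(fs, phi_bar) -
            car_quad(fs, phi_bar, rr) / (2 * t2_bar))
  }

  structure(list(
    kind = kind, n = n, p = p,
    beta = beta_dr, intercept = int_dr, gamma = gamma_dr,
    sigma2 = sigma2_dr, tau2 = tau2_dr, phi = phi_dr, w = w_dr,
    deviance = dev_dr, deviance_at_mean = dev_at_mean,
    post_mean = list(beta = beta_bar, intercept = int_bar,
                     sigma2 = if (kind != "car") s2_bar else NULL,
                     tau2 = if (kind != "independent") t2_bar else NULL,
                     phi = phi_bar,
                     w = if (kind == "geospatial") w_bar else NULL),
    phi_acceptance = if (n_phi > 0) acc_total / n_phi else NA_real_,
    phi_proposal_sd_final = if (kind != "independent") prop_sd else NA_real_,
    band_names = bn, config = cfg, priors = priors,
    selection = selection),
    class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples (", x$kind, "): ", nrow(x$beta), " kept draws, p = ",
      x$p, " bands\n", sep = "")
  cat("  mean model size:", round(mean(rowSums(x$gamma)), 1), "bands\n")
  if (!is.null(x$post_mean$sigma2))
    cat("  E[sigma2 | data] =", signif(x$post_mean$sigma2, 4), "\n")
  if (!is.null(x$post_mean$tau2))
    cat("  E[tau2   | data] =", signif(x$post_mean$tau2, 4), "\n")
  if (!is.na(x$post_mean$phi))
    cat("  E[phi    | data] = ", signif(x$post_mean$phi, 4),
        "  (MH acceptance ", round(100 * x$phi_acceptance), "%)\n", sep = "")
  invisible(x)
}

#' Persist chains as CSV with a JSON sidecar
#'
#' One row per kept draw; scalar parameters and all band coefficients as
#' columns.  The sidecar records the configuration, seed, acceptance rate
#' and effective sample sizes of the scalar parameters.
#'
#' @param samples a `posterior_samples` object.
#' @param path output CSV path; the sidecar is written to `<path>.json`.
#' @export
save_chains <- function(samples, path) {
  df <- data.frame(deviance = samples$deviance, intercept = samples$intercept)
  if (!is.null(samples$sigma2)) df$sigma2 <- samples$sigma2
  if (!is.null(samples$tau2)) df$tau2 <- samples$tau2
  if (!is.null(samples$phi)) df$phi <- samples$phi
  bn <- if (!is.null(samples$band_names)) samples$band_names
  else paste0("beta", seq_len(samples$p))
  bmat <- samples$beta; colnames(bmat) <- bn
  df <- cbind(df, bmat)
  write.csv(df, path, row.names = FALSE)
  scalars <- setdiff(names(df), bn)
  side <- list(kind = samples$kind,
               config = unclass(samples$config),
               phi_acceptance = samples$phi_acceptance,
               ess = lapply(df[scalars], effective_size))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Effective sample size of a chain
#'
#' Initial-positive-sequence estimator from the empirical autocorrelations.
#'
#' @param x numeric vector of MCMC draws.
#' @return Estimated effective sample size.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac < 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(ac))
}

#' Split-half R-hat of a chain
#'
#' Potential scale reduction factor computed from the two halves of a
#' single chain; values near 1 indicate within-chain stationarity.
#'
#' @param x numeric vector of MCMC draws.
#' @return The split R-hat statistic.
#' @export
split_rhat <- function(x) {
  n <- 2L * (length(x) %/% 2L)
  h <- matrix(x[seq_len(n)], ncol = 2)
  m <- n / 2
  W <- mean(apply(h, 2, var))
  B <- m * var(colMeans(h))
  if (W == 0) return(1)
  sqrt(((m - 1) / m * W + B / m) / W)
}
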