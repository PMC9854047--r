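# Small fixtures built in code, shared across test files.

# internal helpers under test
subset_field_for_test <- specar:::subset_field
car_logdet <- specar:::car_logdet
car_quad <- specar:::car_quad

# Dense raw spectrum table for `n_plots`, on a fine grid, from a smooth
# deterministic curve (optionally with noise / missing edges).
toy_raw_spectra <- function(n_plots = 3, lo = 339, hi = 1029, step = 2,
                            noise_sd = 0, edge_na = FALSE, seed = 42) {
  set.seed(seed)
  wl <- seq(lo, hi, by = step)
  rows <- lapply(seq_len(n_plots), function(i) {
    r <- 0.1 + 0.05 * i + 0.2 * exp(-(wl - 550)^2 / (2 * 40^2)) +
      0.3 * stats::plogis((wl - 720) / 15)
    if (noise_sd > 0) r <- r + rnorm(length(wl), 0, noise_sd)
    if (edge_na) r[wl < 460 | wl > 840][sample(c(TRUE, FALSE),
      sum(wl < 460 | wl > 840), replace = TRUE)] <- NA
    data.frame(plot_id = sprintf("P%02d", i), wavelength = wl,
               reflectance = r, stringsAsFactors = FALSE)
  })
  as_raw_spectra(do.call(rbind, rows))
}

# Resampled-spectra object assembled directly from a matrix.
toy_resampled <- function(X, centers = band_grid()) {
  stopifnot(ncol(X) == length(centers))
  if (is.null(rownames(X))) rownames(X) <- sprintf("P%02d", seq_len(nrow(X)))
  structure(list(plot_id = rownames(X), band_centers = centers, X = X),
            class = "resampled_spectra")
}

# Minimal posterior_samples stand-in for summary/prediction tests.
fake_samples <- function(gamma, beta = NULL, kind = "independent",
                         post_mean = NULL, n = NULL) {
  structure(list(gamma = gamma, beta = beta, kind = kind,
                 post_mean = post_mean, n = n,
                 p = ncol(gamma)),
            class = "posterior_samples")
}

# Brute-force conditional mean of a joint normal y ~ N(mu, Sigma) given
# y[train]; the oracle for spatial held-out prediction.
cond_mean_oracle <- function(mu, Sigma, y, train, test) {
  unname(drop(mu[test] + Sigma[test, train, drop = FALSE] %*%
    solve(Sigma[train, train, drop = FALSE], y[train] - mu[train])))
}
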