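test_that("the benchmark design carries the exact planted collinearity", {
  cfg <- simulation_config(seed = 21)
  X <- simulate_design(cfg)
  expect_equal(dim(X), c(126, 150))
  # x101 = x1 + x2 exactly, and so on
  expect_equal(X[, 101], X[, 1] + X[, 2])
  expect_equal(X[, 150], X[, 99] + X[, 100])
  expect_equal(qr(X)$rank, 100)
  expect_identical(simulate_design(cfg), X)
})

test_that("the benchmark coefficient vector matches its printed definition", {
  cfg <- simulation_config()
  beta <- make_beta(cfg)
  expect_equal(beta[2], 0.9)
  expect_equal(beta[1], 0.01)
  expect_equal(sum(beta == 0.9), 12)
  expect_equal(sum(beta), 12 * 0.9 + 138 * 0.01)
})

test_that("responses are drawn from the stated generative models", {
  cfg <- simulation_config(n = 1, seed = 22, sigma2 = 0.3)
  # noiseless null: beta = 0, sigma2 -> 0
  cfg0 <- simulation_config(n = 5, seed = 23, sigma2 = 1e-14,
                            beta_big = 0, beta_small = 0)
  X0 <- simulate_design(cfg0)
  expect_lt(max(abs(simulate_response(cfg0, X0))), 1e-6)

  # model 1 residual variance at one design row over replicate draws
  X1 <- simulate_design(cfg)
  mu <- drop(X1 %*% make_beta(cfg))
  set.seed(24)
  draws <- replicate(10000, simulate_response(cfg, X1, seed = sample.int(2^30, 1)))
  v <- var(drop(draws) - mu)
  mcse <- 0.3 * sqrt(2 / (10000 - 1))
  expect_lt(abs(v - 0.3), 4 * mcse)

  # CAR on the 2-plot layout: empirical covariance vs the explicit inverse
  fs2 <- build_layout(n_rows = 2, n_cols = 1)
  cfg3 <- simulation_config(n = 2, seed = 25, model_kind = "car",
                            beta_big = 0, beta_small = 0)
  X2 <- matrix(0, 2, 150)
  set.seed(26)
  Y <- replicate(10000, simulate_response(cfg3, X2, fs2,
                                          seed = sample.int(2^30, 1)))
  Sigma <- 0.45 * solve(diag(fs2$d_m) - 0.21 * fs2$M)
  expect_equal(unname(cov(t(Y))), unname(Sigma), tolerance = 0.08)

  # phi outside the CAR support is rejected
  cfg_bad <- simulation_config(n = 2, model_kind = "car", phi = 2)
  expect_error(simulate_response(cfg_bad, X2, fs2), "support")
})

test_that("the geostatistical generator has the stated marginal variance", {
  fs <- build_layout(n_rows = 3, n_cols = 2)
  cfg <- simulation_config(n = 6, seed = 27, model_kind = "geospatial",
                           beta_big = 0, beta_small = 0)
  X <- matrix(0, 6, 150)
  set.seed(28)
  Y <- replicate(8000, simulate_response(cfg, X, fs,
                                         seed = sample.int(2^30, 1)))
  # marginal variance = sigma2 + tau2 = 0.75 at every site
  vs <- apply(Y, 1, var)
  expect_equal(unname(vs), rep(0.75, 6), tolerance = 0.1)
  # neighbors are positively correlated through w
  expect_gt(cor(Y[1, ], Y[2, ]), 0.05)
})

test_that("the emulated trial reproduces the split-plot design", {
  cfg <- emulation_config(seed = 31, raw_step = 2)
  trial <- simulate_field_trial(cfg)
  ph <- trial$pheno
  expect_equal(nrow(ph), 126)
  expect_equal(length(unique(ph$genotype)), 21)
  expect_setequal(unique(ph$p_level), c(0, 80))
  expect_equal(length(unique(ph$rep)), 3)
  expect_equal(max(table(ph$genotype, ph$p_level)), 3)
  expect_equal(trial$fs$n, 126)
  expect_true(all(ph$grain_p > 0))
  expect_equal(ph$y, log(ph$grain_p))
  # raw spectra carry edge missingness but a usable window
  raw <- trial$raw
  win <- raw[raw$wavelength >= 450 & raw$wavelength <= 850, ]
  expect_false(anyNA(win$reflectance))
  edge <- raw[raw$wavelength < 449, ]
  expect_gt(mean(is.na(edge$reflectance)), 0.4)
})

test_that("emulation is deterministic and noise-free plots coincide", {
  cfg <- emulation_config(seed = 32, raw_step = 4, noise_plot = 0,
                          noise_vigor = 0, noise_mult = 0, edge_missing = 0)
  t1 <- simulate_field_trial(cfg)
  t2 <- simulate_field_trial(cfg)
  expect_identical(t1$raw$reflectance, t2$raw$reflectance)
  expect_identical(t1$pheno$grain_p, t2$pheno$grain_p)

  # with all noise scales zero, plots sharing genotype and P level have
  # identical spectra
  ph <- t1$pheno
  key <- paste(ph$genotype, ph$p_level)
  dup <- ph$plot_id[key == key[1]]
  expect_gte(length(dup), 2)
  r1 <- t1$raw$reflectance[t1$raw$plot_id == dup[1]]
  r2 <- t1$raw$reflectance[t1$raw$plot_id == dup[2]]
  expect_identical(r1, r2)
})

test_that("the log response carries the active-region signal and spatial field", {
  cfg <- emulation_config(seed = 33, raw_step = 2)
  trial <- simulate_field_trial(cfg)
  wl <- sort(unique(trial$raw$wavelength))
  # responses correlate negatively with active-region reflectance
  act <- trial$raw[trial$raw$wavelength >= 500 & trial$raw$wavelength <= 690, ]
  zbar <- tapply(act$reflectance, act$plot_id, mean, na.rm = TRUE)
  zbar <- zbar[trial$pheno$plot_id]
  expect_lt(cor(trial$pheno$y, zbar), -0.6)
})

test_that("selected bands are enriched in the generative 500-690 nm region", {
  # full pipeline at reduced chain length: resample, CAR fit with the
  # moderate inclusion prior (prior expected model size ~half the bands),
  # PIP >= 0.6 selection; median enrichment over 3 seeds
  frac <- vapply(33:35, function(sd) {
    cfg <- emulation_config(seed = sd, raw_step = 2)
    tr <- simulate_field_trial(cfg)
    sp <- resample_bsplines(filter_window(tr$raw, 450, 850))
    ds <- assemble_dataset(sp, tr$pheno)
    pr <- list(beta = spike_slab_prior(p0 = 0.5), tau2 = variance_prior(),
               phi = phi_prior(tr$fs$phi_support[1], tr$fs$phi_support[2]))
    f <- fit_model(ds$y, ds$X, "car", fs = tr$fs, priors = pr,
                   cfg = mcmc_config(n_iter = 6000, burn_in = 2000,
                                     thin = 2, seed = 9))
    sel <- selection_summary(f)
    selb <- sp$band_centers[sel$selected_threshold]
    expect_gt(length(selb), 0)
    mean(selb >= 500 & selb <= 690)
  }, numeric(1))
  expect_gte(median(frac), 0.7)
})
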