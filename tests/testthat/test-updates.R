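# Closed-form posterior inclusion probability for one coordinate with
# error precision 1/s2, slab N(mu, nu), exclusion prior p0, predictor x
# orthogonal to everything else in the model and residual r.
pin_closed_form <- function(x, r, s2, p0, mu = 0, nu = 1) {
  a <- sum(x * x) / s2
  b <- sum(x * r) / s2
  v <- 1 / (a + 1 / nu)
  m <- v * (b + mu / nu)
  logBF <- 0.5 * log(v / nu) + 0.5 * (m^2 / v - mu^2 / nu)
  1 / (1 + exp(-(log((1 - p0) / p0) + logBF)))
}

test_that("a degenerate slab makes inclusion revert to its prior probability", {
  set.seed(1)
  n <- 20
  data <- list(y = rnorm(n), X = matrix(rnorm(n), n, 1))
  prior <- spike_slab_prior(p0 = 0.7, mu = 0, nu = 1e-12)
  st0 <- specar:::new_state("independent", data$y, data$X)
  st0$sigma2 <- 1
  g <- replicate(2000, update_beta_gamma(st0, data, prior)$gamma)
  expect_lt(abs(mean(g) - 0.3), 0.045)  # 4+ binomial MCSEs
})

test_that("inclusion frequencies match the closed-form conjugate posterior", {
  set.seed(2)
  n <- 40
  # centered orthogonal predictors: coordinates decouple exactly, so the
  # chain's marginal inclusion frequencies must match the scalar formula
  x1 <- scale(rnorm(n), scale = FALSE)
  x2 <- residuals(lm(rnorm(n) ~ x1))
  X <- cbind(drop(x1), drop(x2))
  y <- drop(0.35 * X[, 1] + rnorm(n, 0, 0.9))
  y <- y - mean(y)
  s2 <- 0.8
  prior <- spike_slab_prior(p0 = 0.5, mu = 0, nu = 1)
  data <- list(y = y, X = X)
  st0 <- specar:::new_state("independent", y, X)
  st0$sigma2 <- s2
  G <- replicate(3000, update_beta_gamma(st0, data, prior)$gamma)
  freq <- rowMeans(G)
  expected <- c(pin_closed_form(X[, 1], y, s2, 0.5),
                pin_closed_form(X[, 2], y, s2, 0.5))
  mcse <- sqrt(expected * (1 - expected) / 3000)
  expect_lt(abs(freq[1] - expected[1]), 5 * mcse[1] + 1e-3)
  expect_lt(abs(freq[2] - expected[2]), 5 * mcse[2] + 1e-3)

  # a very strong signal is (almost) always included
  ystrong <- drop(3 * X[, 1] + rnorm(n, 0, 0.3)); ystrong <- ystrong - mean(ystrong)
  expect_gt(pin_closed_form(X[, 1], ystrong, 0.3^2, 0.5), 0.999)
  stS <- st0; stS$sigma2 <- 0.3^2
  GS <- replicate(500, update_beta_gamma(stS, list(y = ystrong, X = X),
                                         prior)$gamma[1])
  expect_gt(mean(GS), 0.95)
})

test_that("included coefficients are normal draws, excluded ones exact zeros", {
  set.seed(4)
  n <- 30
  X <- matrix(rnorm(n * 3), n, 3)
  y <- drop(X %*% c(2, 0, -2)) + rnorm(n, 0, 0.5)
  st <- specar:::new_state("independent", y, X)
  st$sigma2 <- 0.25
  data <- list(y = y, X = X)
  pr <- spike_slab_prior(p0 = 0.5)
  for (i in 1:50) {
    st <- update_beta_gamma(st, data, pr)
    expect_identical(st$beta == 0, st$gamma == 0L)
  }
})

test_that("variance updates follow the conjugate inverse gamma", {
  set.seed(5)
  # zero residuals: conditional is IG(alpha + n/2, eta) with unchanged rate
  n <- 12
  X <- matrix(rnorm(n * 2), n, 2)
  beta <- c(1, -1)
  st <- specar:::new_state("independent", drop(X %*% beta), X)
  st$beta <- beta; st$intercept <- 0
  data0 <- list(y = drop(X %*% beta), X = X)
  pr <- list(sigma2 = variance_prior(0.01, 0.01))
  draws <- replicate(4000, update_variances(st, data0, pr)$sigma2)
  sh <- 0.01 + n / 2; rt <- 0.01
  # 1/sigma2 ~ Gamma(sh, rt): compare the precision mean at 4 MCSEs
  expect_lt(abs(mean(1 / draws) - sh / rt), 4 * sqrt(sh) / rt / sqrt(4000))

  # fixed nonzero residuals, n = 100: draws average to the IG mean
  n <- 100
  X <- matrix(rnorm(n), n, 1)
  y <- rnorm(n)
  st <- specar:::new_state("independent", y, X)
  st$beta <- 0.3; st$intercept <- 0.1
  r <- y - 0.1 - 0.3 * X[, 1]
  sh <- 0.01 + n / 2; rt <- 0.01 + sum(r^2) / 2
  draws <- replicate(10000, update_variances(st, list(y = y, X = X), pr)$sigma2)
  igmean <- rt / (sh - 1)
  expect_lt(abs(mean(draws) - igmean), 4 * sd(draws) / sqrt(10000))
})

test_that("the CAR quadratic form expands to its scalar formula on two plots", {
  fs <- build_layout(n_rows = 2, n_cols = 1)
  r <- c(0.7, -1.2)
  expect_equal(car_quad(fs, 0, r), sum(fs$d_m * r^2))
  expect_equal(car_quad(fs, 0.4, r), r[1]^2 + r[2]^2 - 2 * 0.4 * r[1] * r[2])
})

test_that("a zero proposal scale leaves phi unchanged", {
  fs <- build_layout(n_rows = 2, n_cols = 2)
  st <- specar:::new_state("car", rnorm(4), matrix(rnorm(4), 4, 1), fs)
  st$tau2 <- 1
  data <- list(y = rnorm(4), X = matrix(0, 4, 1))
  pr <- phi_prior(fs$phi_support[1], fs$phi_support[2])
  phis <- replicate(50, update_phi_mh(st, data, fs, pr, proposal_sd = 0)$phi)
  expect_true(all(phis == st$phi))
})

test_that("a flat phi target yields a uniform stationary distribution", {
  set.seed(6)
  fs <- build_layout(n_rows = 2, n_cols = 2)
  st <- specar:::new_state("car", rnorm(4), matrix(rnorm(4), 4, 1), fs)
  pr <- phi_prior(0, 1)
  st$phi <- 0.5
  data <- list(y = rnorm(4), X = matrix(0, 4, 1))
  flat <- function(phi) 0
  draws <- numeric(10000); acc <- 0
  for (i in seq_len(10000)) {
    st <- update_phi_mh(st, data, fs, pr, proposal_sd = 2, log_target = flat)
    draws[i] <- st$phi
    acc <- acc + st$phi_accepted
  }
  ks <- suppressWarnings(stats::ks.test(draws[seq(1, 10000, by = 20)],
                                        "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(acc / 10000, 0.5)
})

test_that("the phi chain matches the exact grid posterior (CAR, 3-plot chain)", {
  set.seed(7)
  fs <- build_layout(n_rows = 3, n_cols = 1)
  # strongly correlated residuals favour positive phi
  r <- c(1.1, 1.0, 1.2)
  st <- specar:::new_state("car", r, matrix(0, 3, 1), fs)
  st$beta <- 0; st$intercept <- 0; st$tau2 <- 0.4
  data <- list(y = r, X = matrix(0, 3, 1))
  pr <- phi_prior(fs$phi_support[1], fs$phi_support[2])
  draws <- numeric(20000)
  for (i in seq_len(20000)) {
    st <- update_phi_mh(st, data, fs, pr, proposal_sd = 1.2)
    draws[i] <- st$phi
  }
  draws <- draws[-(1:2000)]
  # exact posterior by quadrature over the support
  grid <- seq(pr$lo + 1e-4, pr$hi - 1e-4, length.out = 2000)
  lp <- vapply(grid, function(ph)
    0.5 * car_logdet(fs, ph) - car_quad(fs, ph, r) / (2 * st$tau2),
    numeric(1))
  wts <- exp(lp - max(lp)); wts <- wts / sum(wts)
  expect_equal(mean(draws), sum(grid * wts), tolerance = 0.03)
  expect_equal(mean(draws > 0), sum(wts[grid > 0]), tolerance = 0.03)
  expect_gt(mean(draws > 0), 0.9)  # positive dependence is detected
})

test_that("latent-field update has the closed bivariate conditional", {
  set.seed(8)
  fs <- build_layout(n_rows = 2, n_cols = 1, plot_dy = 2)
  y <- c(1.4, -0.6); X <- matrix(c(0.3, -0.2), 2, 1)
  st <- specar:::new_state("geospatial", y, X, fs)
  st$beta <- 0.5; st$intercept <- 0.2; st$sigma2 <- 0.9
  st$tau2 <- 0.5; st$phi <- 0.3
  data <- list(y = y, X = X)
  W <- replicate(6000, update_w(st, data, fs)$w)
  H <- exp_correlation(distance_matrix(fs), 0.3)
  A <- solve(H) / 0.9 + diag(2) / 0.5
  Sig <- solve(A)
  m <- unname(drop(Sig %*% ((y - 0.2 - drop(X %*% 0.5)) / 0.5)))
  expect_equal(rowMeans(W), m, tolerance = 4 * sqrt(max(diag(Sig)) / 6000) + 0.01)
  expect_equal(unname(cov(t(W))), unname(Sig), tolerance = 0.05)
})

test_that("latent field collapses when either variance vanishes", {
  set.seed(9)
  fs <- build_layout(n_rows = 2, n_cols = 2)
  y <- rnorm(4); X <- matrix(rnorm(4), 4, 1)
  st <- specar:::new_state("geospatial", y, X, fs)
  st$phi <- 0.2; st$beta <- 0.3; st$intercept <- 0
  data <- list(y = y, X = X)
  st$sigma2 <- 1e-10; st$tau2 <- 1
  expect_lt(sqrt(sum(update_w(st, data, fs)$w^2)), 1e-4)
  st$sigma2 <- 1; st$tau2 <- 1e-10
  expect_equal(update_w(st, data, fs)$w, y - 0.3 * X[, 1],
               tolerance = 1e-3)
})
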