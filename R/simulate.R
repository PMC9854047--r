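#' Configuration of the simulation benchmark
#'
#' The benchmark design: 100 iid standard-normal predictors plus 50 exact
#' pairwise sums (planted multicollinearity), 150 columns in all; twelve
#' "big" coefficients of 0.9 on the index set `A`, 0.01 elsewhere; variance
#' parameters `sigma2 = 0.3`, `tau2 = 0.45`, spatial dependence
#' `phi = 0.21`.
#'
#' @param n number of plots (default 126).
#' @param seed RNG seed.
#' @param model_kind which generative model the response follows.
#' @param big_set indices of the large coefficients.
#' @param beta_big,beta_small the two coefficient values.
#' @param sigma2,tau2,phi variance and spatial-dependence parameters.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n = 126, seed = 1,
                              model_kind = c("independent", "geospatial",
                                             "car"),
                              big_set = c(2, 6, 13, 25, 33, 67, 71, 77, 85,
                                          94, 96, 99),
                              beta_big = 0.9, beta_small = 0.01,
                              sigma2 = 0.3, tau2 = 0.45, phi = 0.21) {
  model_kind <- match.arg(model_kind)
  big_set <- sort(big_set)
  stopifnot(all(big_set >= 1), all(big_set <= 150), length(big_set) == 12,
            sigma2 > 0, tau2 > 0)
  structure(list(n = n, seed = seed, model_kind = model_kind,
                 big_set = big_set, beta_big = beta_big,
                 beta_small = beta_small, sigma2 = sigma2, tau2 = tau2,
                 phi = phi, p = 150L),
            class = "simulation_config")
}

#' Simulate the benchmark design matrix
#'
#' Columns 1--100 are iid standard normal; column `100 + m` equals column
#' `2m - 1` plus column `2m` for `m = 1..50` (exact linear combinations, so
#' the 150-column matrix has rank 100).
#'
#' @param cfg a [simulation_config()].
#' @return An `n` x 150 matrix with columns `x1..x150`.
#' @export
simulate_design <- function(cfg) {
  set.seed(cfg$seed)
  Z <- matrix(rnorm(cfg$n * 100L), cfg$n, 100L)
  extra <- Z[, seq(1, 99, by = 2), drop = FALSE] +
    Z[, seq(2, 100, by = 2), drop = FALSE]
  X <- cbind(Z, extra)
  colnames(X) <- paste0("x", seq_len(150L))
  X
}

#' Benchmark coefficient vector
#'
#' `beta_j = 0.9` on the big set, `0.01` on the remaining 138 indices.
#'
#' @param cfg a [simulation_config()].
#' @return Numeric vector of length 150.
#' @export
make_beta <- function(cfg) {
  beta <- rep(cfg$beta_small, 150L)
  beta[cfg$big_set] <- cfg$beta_big
  beta
}

#' Simulate a response under one of the three generative models
#'
#' * independent: `y = X beta + eps`, `eps ~ N(0, sigma2 I)`;
#' * geostatistical: `y = X beta + w + eps`, `w ~ N(0, sigma2 H(phi))`,
#'   `eps ~ N(0, tau2 I)`;
#' * CAR: `y ~ N(X beta, tau2 (D_M - phi M)^{-1})`, drawn through the
#'   Cholesky factor of the precision (no explicit inverse).
#'
#' @param cfg a [simulation_config()] (fields `model_kind`, `sigma2`,
#'   `tau2`, `phi`).
#' @param X design matrix.
#' @param fs `field_structure` (spatial kinds); `cfg$phi` must lie inside
#'   `fs$phi_support` for the CAR kind.
#' @param seed RNG seed; defaults to `cfg$seed + 1` so a design drawn with
#'   `cfg$seed` and its response use disjoint random streams.
#' @return Numeric response vector of length `nrow(X)`.
#' @export
simulate_response <- function(cfg, X, fs = NULL, seed = cfg$seed + 1) {
  set.seed(seed)
  n <- nrow(X)
  mu <- drop(X %*% make_beta(cfg))
  if (cfg$model_kind == "independent")
    return(mu + rnorm(n, 0, sqrt(cfg$sigma2)))
  if (is.null(fs)) stop("spatial simulation needs a field_structure")
  stopifnot(fs$n == n)
  if (cfg$model_kind == "geospatial") {
    H <- exp_correlation(distance_matrix(fs), cfg$phi)
    w <- drop(crossprod(chol(cfg$sigma2 * H), rnorm(n)))
    return(mu + w + rnorm(n, 0, sqrt(cfg$tau2)))
  }
  if (cfg$phi <= fs$phi_support[1] || cfg$phi >= fs$phi_support[2])
    stop("cfg$phi outside the CAR support of the layout")
  Q <- diag(fs$d_m) - cfg$phi * fs$M
  R <- chol(Q)                       # Q = R'R; cov = tau2 Q^{-1}
  mu + sqrt(cfg$tau2) * backsolve(R, rnorm(n))
}

#' Configuration of the emulated hyperspectral field trial
#'
#' Emulates a split-plot phosphorus trial: 2 fertilization levels (main
#' plots) x 21 genotypes (subplots) x 3 replicates = 126 plots, each with a
#' smooth canopy reflectance spectrum on a fine sensor grid, genotype and
#' fertilization effects concentrated in the 500--690 nm (green-to-red)
#' region through canopy chlorophyll, log-normal grain phosphorus driven by
#' that same region, and a CAR-distributed spatial field on the plot grid.
#'
#' @param n_genotypes,reps,p_levels split-plot design parameters.
#' @param raw_lo,raw_hi,raw_step raw sensor wavelength grid (nm).
#' @param active_lo,active_hi region (nm) carrying the phosphorus signal.
#' @param genotype_sd genotype effect scale on canopy chlorophyll.
#' @param p_shift chlorophyll shift of the fertilized level.
#' @param noise_plot per-plot chlorophyll noise sd (0 for deterministic
#'   spectra given genotype and level).
#' @param noise_vigor per-plot NIR vigor noise sd.
#' @param noise_mult multiplicative spectral noise sd (log scale).
#' @param p_intercept,p_slope intercept and slope of the log grain
#'   phosphorus response on the plot's mean active-region reflectance.
#' @param tau2_field,phi_field CAR parameters of the spatial field in the
#'   log response.
#' @param edge_missing probability that a raw band outside the usable
#'   449--852 nm range is missing (emulating the sensor edge dropout that
#'   motivates the 450--850 nm analysis window).
#' @param seed RNG seed.
#' @return An `emulation_config` list.
#' @export
emulation_config <- function(n_genotypes = 21, reps = 3, p_levels = c(0, 80),
                             raw_lo = 339, raw_hi = 1029, raw_step = 0.38,
                             active_lo = 500, active_hi = 690,
                             genotype_sd = 0.06, p_shift = 0.10,
                             noise_plot = 0.03, noise_vigor = 0.2,
                             noise_mult = 0.03,
                             p_intercept = 3.6, p_slope = -18,
                             tau2_field = 0.05, phi_field = 0.21,
                             edge_missing = 0.65, seed = 1) {
  structure(list(n_genotypes = n_genotypes, reps = reps, p_levels = p_levels,
                 raw_lo = raw_lo, raw_hi = raw_hi, raw_step = raw_step,
                 active_lo = active_lo, active_hi = active_hi,
                 genotype_sd = genotype_sd, p_shift = p_shift,
                 noise_plot = noise_plot, noise_vigor = noise_vigor,
                 noise_mult = noise_mult,
                 p_intercept = p_intercept, p_slope = p_slope,
                 tau2_field = tau2_field, phi_field = phi_field,
                 edge_missing = edge_missing, seed = seed,
                 n = length(p_levels) * n_genotypes * reps),
            class = "emulation_config")
}

# Smooth canopy reflectance curve.  chl in (0,1) deepens the green-to-red
# (500-690 nm) reflectance bumps -- the only chl-dependent terms, so the
# nutrient signal stays confined to that region; vigor shifts the NIR
# plateau independently of chl.
canopy_spectrum <- function(wl, chl, vigor) {
  green_peak <- exp(-(wl - 560)^2 / (2 * 28^2))
  red_shoulder <- exp(-(wl - 650)^2 / (2 * 22^2))
  red_edge <- stats::plogis((wl - 715) / 12)
  base <- 0.045 +
    0.16 * (1 - chl) * (green_peak + 0.6 * red_shoulder) +
    (0.42 + 0.10 * vigor) * red_edge
  pmax(base, 0.005)
}

#' Simulate an emulated hyperspectral field trial
#'
#' Generates the full raw-data bundle the pipeline consumes: a raw spectra
#' table on the fine sensor grid with edge-band missingness, a phenotype
#' table with log-normal grain phosphorus, and the field structure (21 x 6
#' rook grid; each column of the grid is one replicate-by-fertilization
#' main plot carrying all genotypes in randomized order).  The log response
#' is a linear function of the plot's mean reflectance over the active
#' region plus a CAR-distributed spatial field, so it follows the CAR
#' generative structure by construction.
#'
#' @param cfg an [emulation_config()].
#' @return List with `raw` (a `raw_spectra` table), `pheno` (a `phenotype`
#'   table), `fs` (a `field_structure`), and `truth` (the latent per-plot
#'   chlorophyll, vigor and spatial field).
#' @export
simulate_field_trial <- function(cfg = emulation_config()) {
  set.seed(cfg$seed)
  n_cols <- length(cfg$p_levels) * cfg$reps
  fs <- build_layout(n_rows = cfg$n_genotypes, n_cols = n_cols)
  n <- fs$n
  # treatment assignment: grid column -> (rep, p_level); genotype order
  # randomized within each column
  col_of <- fs$layout$col
  rep_of_col <- rep(seq_len(cfg$reps), each = length(cfg$p_levels))
  lev_of_col <- rep(cfg$p_levels, times = cfg$reps)
  genotype <- integer(n)
  for (cc in seq_len(n_cols))
    genotype[col_of == cc] <- sample.int(cfg$n_genotypes)
  p_level <- lev_of_col[col_of]
  rep_id <- rep_of_col[col_of]

  g_eff <- rnorm(cfg$n_genotypes, 0, cfg$genotype_sd)
  v_eff <- rnorm(cfg$n_genotypes, 0, 0.5)
  chl <- 0.50 + g_eff[genotype] +
    cfg$p_shift * (p_level > 0) +
    rnorm(n, 0, cfg$noise_plot)
  chl <- pmin(pmax(chl, 0.15), 0.95)
  vigor <- v_eff[genotype] + rnorm(n, 0, cfg$noise_vigor)

  wl <- seq(cfg$raw_lo, cfg$raw_hi, by = cfg$raw_step)
  nb <- length(wl)
  refl <- matrix(NA_real_, n, nb)
  for (i in seq_len(n)) {
    r <- canopy_spectrum(wl, chl[i], vigor[i])
    if (cfg$noise_mult > 0)
      r <- r * exp(rnorm(nb, 0, cfg$noise_mult))
    refl[i, ] <- r
  }
  # edge-band dropout outside the usable window
  edge <- wl < 449 | wl > 852
  if (cfg$edge_missing > 0 && any(edge)) {
    drop_mask <- matrix(runif(n * sum(edge)) < cfg$edge_missing, n)
    refl[, edge][drop_mask] <- NA_real_
  }

  # log grain phosphorus: active-region reflectance signal + CAR field
  active <- wl >= cfg$active_lo & wl <= cfg$active_hi
  zbar <- rowMeans(refl[, active, drop = FALSE], na.rm = TRUE)
  Q <- diag(fs$d_m) - cfg$phi_field * fs$M
  u <- sqrt(cfg$tau2_field) * backsolve(chol(Q), rnorm(n))
  y <- cfg$p_intercept + cfg$p_slope * zbar + u
  pheno <- as_phenotype(data.frame(
    plot_id = fs$plot_ids, year = 2010L,
    genotype = sprintf("G%02d", genotype),
    p_level = p_level, rep = rep_id, grain_p = exp(y),
    stringsAsFactors = FALSE))

  raw <- as_raw_spectra(data.frame(
    plot_id = rep(fs$plot_ids, each = nb),
    wavelength = rep(wl, times = n),
    reflectance = as.vector(t(refl)),
    stringsAsFactors = FALSE))

  list(raw = raw, pheno = pheno, fs = fs,
       truth = list(chl = chl, vigor = vigor, spatial = drop(u),
                    genotype = genotype))
}
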