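---
title: "Bayesian band selection for grain phosphorus: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian band selection for grain phosphorus: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`specar` models the grain phosphorus concentration of field-trial wheat from
plot-level hyperspectral canopy reflectance. The response is
$y_i = \log(\text{grain P}_i)$; the predictors are reflectance values at
spectral bands. Three error structures are fitted and compared, each with
spike-and-slab priors on the band coefficients so that band selection is part
of the fit itself.

## The three models

**Independent errors.** $y_i = \beta_0 + x_i^\top\beta + \epsilon_i$ with
$\epsilon_i \sim N(0, \sigma^2)$ iid.

**Geostatistical.** $y_i = \beta_0 + x_i^\top\beta + w_i + \epsilon_i$ with a
latent spatial field $w \sim N(0, \sigma^2 H(\phi))$,
$H(\phi)_{ij} = \exp(-\phi\,\lVert s_i - s_j\rVert)$ on the plot centroids
$s_i$ (metres), and nugget $\epsilon_i \sim N(0, \tau^2)$. Here $\sigma^2$ is
the partial sill and $\tau^2$ the nugget; $\phi > 0$ is the correlation decay
rate per metre with a $U(0, 1)$ prior. We read the variance roles this way —
field variance $\sigma^2$, residual variance $\tau^2$ — because the sampling
model conditions on $w$ with variance $\tau^2$. For DIC, however, the
geostatistical deviance integrates the latent field out,
$y \sim N(X\beta,\ \sigma^2 H(\phi) + \tau^2 I)$: scoring the $w$-conditional
likelihood lets the field absorb the residuals and drives the conditional DIC
below that of *both* other models on every dataset we simulated — a known
pathology of latent-variable DIC with conditional focus — so all three model
kinds are compared on marginal likelihoods of the same data.

**Conditionally autoregressive (CAR).** The joint form
$y \sim N(X\beta,\; \tau^2 (D_M - \phi M)^{-1})$, where $M$ is the binary rook
adjacency of the plot grid ($m_{ij} = 1$ when plots share an edge),
$D_M = \mathrm{diag}(m_{i\cdot})$ holds the neighbor counts, and $\phi$
measures conditional spatial dependence. A per-site conditional variance of
the form $\tau^2(\sum_j m_{ij} - \phi m_{i\cdot})^{-1}$ does not define a
consistent joint distribution, so the package works with the joint form
throughout. Valid $\phi$ lie in the open interval
$(1/\lambda_{(1)},\, 1/\lambda_{(n)})$, where
$\lambda_{(1)} < 0 < \lambda_{(n)}$ are the extreme eigenvalues of the
*symmetrically scaled* adjacency $D_M^{-1/2} M D_M^{-1/2}$; this scaling (not
$D_M^{1/2} M D_M^{1/2}$) is what yields the standard bounds, and the uniform
prior on $\phi$ uses exactly that interval. All CAR determinants and quadratic
forms are evaluated through the eigenvalues of the scaled adjacency — never an
explicit matrix inverse — using
$\log\det(D_M - \phi M) = \sum_i \log m_{i\cdot} + \sum_i \log(1 - \phi \lambda_i)$.

## Spike-and-slab band selection

Each band coefficient has the mixture prior
$p(\beta_j \mid \gamma_j) = (1-\gamma_j)\,\delta_0(\beta_j) + \gamma_j\,N(\mu_j, \nu_j)$
with $P(\gamma_j = 0) = p_0$. The Gibbs update integrates $\beta_j$ out
against the slab when drawing $\gamma_j$ (a scalar Bayes factor against the
point mass), then draws $\beta_j$ from its conjugate normal when included —
so excluded coefficients are *exactly* zero in every draw, and the posterior
inclusion probability (PIP) of band $j$ is the posterior mean of $\gamma_j$.

Defaults, and why:

* predictors are standardized internally (mean 0, unit variance); the slab is
  $N(0, 1)$ on that scale, a unit-information choice. Coefficients are
  back-transformed for reporting.
* $p_0 = 0.9$, i.e. a prior expected model size of about 10% of the bands.
  With more candidate bands than plots and strong between-band collinearity,
  an indifferent $p_0 = 0.5$ admits enough spurious bands that the residual
  variance is visibly absorbed (we measured posterior means of $\sigma^2$
  around 0.20 on benchmark data generated with $\sigma^2 = 0.3$); nutrient
  signal in canopy spectra is carried by a small subset of wavelengths, and
  the sparser default recovers the generating variances. $p_0$ is a plain
  argument, and analyses that expect many correlated bands to share the
  signal (e.g. the emulated-trial demonstration below) may prefer 0.5.
* the intercept is always included, never selected over, and carries a
  near-flat $N(0, 10^6)$ prior.
* variance components have $IG(\alpha = 0.01, \eta = 0.01)$ priors (shape /
  rate; weakly informative).

Two selection criteria summarize a fit: bands with PIP $\ge 0.6$, and the
most probable submodel (*avgmod*), the $\gamma$ configuration with the highest
exact-match frequency among the kept draws (frequency ties broken toward the
smaller model, then lexicographically).

## Sampling

One sweep per iteration: coefficients ($\beta,\gamma$ jointly, coordinate
order randomized each sweep to reduce sticking under collinearity), variance
components (conjugate inverse gamma), $\phi$ (Metropolis–Hastings), the
latent field $w$ (multivariate normal, Cholesky solve). The $\phi$ update is
a Gaussian random walk on the logit of $(\phi - \text{lo})/(\text{hi} -
\text{lo})$ with Jacobian-corrected acceptance; the proposal scale (default
0.25) is adapted every 50 burn-in iterations toward a 20–50% acceptance rate
and frozen afterwards to preserve detailed balance. Initialization:
$\beta = 0$, $\gamma \equiv 1$, variances at $\mathrm{var}(y)$, $\phi$ at the
support midpoint, $w = 0$. Chains are a deterministic function of the seed.

The coefficient sweep is implemented in C++ (using R's RNG) because it is the
hot loop; all conditionals are conjugate closed forms, so no external MCMC
engine is involved. The per-draw deviance is stored for DIC:
$\mathrm{DIC} = \bar D + p_D$, $p_D = \bar D - D(\bar\theta)$, with
$D(\bar\theta)$ evaluated at the posterior means.

## Spectral preprocessing

Raw spectra are windowed to 450–850 nm and resampled to a 4 nm grid
(450, 454, …, 850 — exactly 101 bands) with a penalized cubic B-spline per
plot: basis on equally spaced interior knots, second-order difference penalty,
smoothing parameter chosen by GCV over a log-spaced grid whose lower endpoint
is effectively zero. That lower endpoint matters: it makes noiseless spectra
(polynomials in particular) reproduce to ~1e-10 relative, which the package
treats as a contract of the resampler. Missing raw bands are dropped per plot
before fitting; band centers are clamped to the observed range when they fall
within 2 nm of its boundary (windowed raw grids rarely contain the window
endpoints exactly), and anything farther out is an extrapolation error.
Resampled reflectance is clamped to $[0, 1.5]$ (white-reference calibration
can mildly exceed 1), with a warning naming the affected plots.

## Field layout

The emulated trial uses 126 plots on a 21-row × 6-column grid of 3.2 m × 5 m
plot centroids with rook adjacency (queen available as a switch); each grid
column is one replicate-by-fertilization main plot carrying all 21 genotypes
in randomized order. The true trial arrangement is not public, so this layout
is an explicit emulation and is overridable by a `(plot_id, row, col)` CSV.

## Cross-validation

25 of 126 plots are held out uniformly at random, 5 repeats. Fits use
*training rows only*: for the CAR model the training likelihood uses the
field precision restricted to the training plots — a valid Gaussian in its
own right, positive definite over the full-field $\phi$ support by eigenvalue
interlacing (the restricted scaled adjacency is a principal submatrix of the
full one). Held-out plots are predicted at the posterior means: the CAR
conditional mean via the partitioned full-field precision,
$\hat y_{\text{te}} = \mu_{\text{te}} - Q_{22}^{-1} Q_{21} (y_{\text{tr}} -
\mu_{\text{tr}})$, and the geostatistical one by simple kriging of the
posterior-mean latent field. Plug-in prediction at posterior means (rather
than full posterior predictive draws) matches the point-estimate usage of the
evaluation tables. The restricted-band table cells ("PIP ≥ 0.6", "avgmod")
are *refits* on the selected bands with selection disabled, not reuses of the
full-model chains.

Vegetation-index baselines (SR, NDVI, GNDVI, SAVI, OSAVI) are computed from
the same resampled spectra and correlated with $y$ on the same held-out sets.
Range subscripts such as $R_{800-900}$ average the bands inside the range,
truncated to the available grid (800–850 on a 450–850 nm grid); single
subscripts map to the nearest band center, ties to the lower one. SAVI and
OSAVI default to the forms with the leading constant on the first numerator
term only, as tabulated in the nutrient-monitoring comparison this package
reproduces; `veg_indices(canonical = TRUE)` switches to the textbook forms
that multiply the whole difference.

## The synthetic generators

**Benchmark design** (`simulate_design()` / `simulate_response()`): 100 iid
standard-normal predictors plus 50 exact pairwise sums (planted
multicollinearity; the 150-column matrix has rank 100), twelve coefficients
of 0.9 on the index set {2, 6, 13, 25, 33, 67, 71, 77, 85, 94, 96, 99}
(stored sorted), 0.01 elsewhere, and $\sigma^2 = 0.3$, $\tau^2 = 0.45$,
$\phi = 0.21$ for the three generative models. On the 21 × 6 rook layout the
CAR support is approximately $(-1.005, 1.024)$, so $\phi = 0.21$ is a *weak*
dependence: the exact posterior of $\phi$ given the true coefficients has a
standard deviation of about 0.21. Two consequences worth knowing: variance
recovery is solid ($\sigma^2$ within 20%, $\tau^2$ within 25%, across seeds),
but DIC comparisons between the CAR and independent fits on such data ride on
a small expected gap (a few deviance units, mostly from neighbor-count
heteroscedasticity) with a larger across-dataset spread, so the CAR fit is
not guaranteed to win on every replicate.

**Emulated trial** (`simulate_field_trial()`): smooth canopy spectra on the
fine sensor grid (339–1029 nm at 0.38 nm) built from a green peak (560 nm), a
red shoulder (650 nm) and a logistic red edge into an NIR plateau. Canopy
chlorophyll — moved by genotype (sd 0.06), fertilization (+0.10 for the
fertilized level) and plot noise (sd 0.03) — scales only the 500–690 nm
bumps, so the nutrient signal is confined to that region by construction; an
independent "vigor" effect moves the NIR plateau so that near-infrared bands
are realistic but uninformative. Multiplicative spectral noise is 3%
(log-scale sd 0.03), typical of field spectroradiometry and enough to keep
neighboring bands from being exact duplicates. Bands outside 449–852 nm are
missing with probability 0.65, emulating the sensor edge dropout that
motivates the 450–850 nm window. Log grain phosphorus is linear in the plot's
mean active-region reflectance (slope −18, intercept 3.6, giving grain P
around 3.5 mg/g and a reflectance–response correlation near −0.85) plus a CAR
field ($\tau^2 = 0.05$, $\phi = 0.21$), so the response follows the CAR
generative structure. What the emulation does *not* attempt: radiative
transfer realism, weather or soil covariates, genotype-by-year structure.
Passing tests on emulated data show the pipeline recovers structure it
planted; they cannot certify performance on real canopy spectra.

## Numerical choices and degenerate inputs

* CAR positive definiteness is enforced by the open $\phi$ support; at the
  support edge the precision is singular and is rejected.
* `exp_correlation()` requires $\phi > 0$; the latent-field update reports a
  condition-number error if $H(\phi)$ is numerically ill-conditioned.
* Deviance draws must be finite; a divergent chain aborts with the iteration
  index.
* Empty selected-band sets in the pipeline produce `NA` cells with a warning
  rather than an intercept-only refit.
* An index with a zero denominator yields `NA` for that plot (warned); a
  constant index on a test set drops that repeat from the CV mean (warned).
* Chain lengths in the examples and tests are reduced (typically 10,000
  iterations, 5,000 burn-in, thin 5, and shorter for smoke tests) — chosen as
  the package's desk-scale default; `mcmc_config(100000, 50000, 5)`
  reproduces the full-length analysis of the original study design.

## Known limitations

* $\phi$ in the CAR model is weakly identified at low true dependence; its
  posterior mean is a poor point summary there (the sign and the credible
  interval are more stable).
* Spike-and-slab PIPs dilute across near-duplicate bands; with the sparse
  default prior on strongly collinear spectra, the union of a correlated
  group can be included almost surely while no single band reaches the 0.6
  threshold. The avgmod criterion and the PIP *profile* (not only the
  thresholded set) should be read together.
* The splits are uniformly random, not spatially blocked; spatial CV blocking
  is out of scope.
* DIC is the only fit criterion implemented (no WAIC/LOO).
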