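# specar

Bayesian spectral band selection with spatial models, for predicting grain
phosphorus in wheat field trials from hyperspectral canopy reflectance.

Determining grain phosphorus chemically is slow and expensive; canopy
reflectance is cheap and fast. This package models
$y_i = \log(\text{grain P}_i)$ of each field plot from its reflectance at
101 spectral bands (450–850 nm, 4 nm bandwidth), selecting the informative
bands as part of the fit, and accounting for the spatial layout of the trial.
It is aimed at plant-phenotyping and agricultural-statistics workflows where
plots sit on a grid and neighboring plots are correlated.

## The models

Each band coefficient carries a spike-and-slab prior
$p(\beta_j \mid \gamma_j) = (1-\gamma_j)\,\delta_0 + \gamma_j\,N(\mu_j,\nu_j)$,
so a band's posterior inclusion probability (PIP) is
$p(\beta_j \neq 0 \mid \text{data}) = E[\gamma_j \mid \text{data}]$. Three
error structures are fitted by Gibbs sampling (Metropolis–Hastings for the
spatial dependence parameter $\phi$) and compared by DIC:

| kind | model |
|---|---|
| independent | $y_i = \beta_0 + x_i^\top\beta + \epsilon_i$, $\epsilon_i \sim N(0,\sigma^2)$ |
| geospatial | adds $w \sim N(0, \sigma^2 H(\phi))$, $H_{ij} = e^{-\phi\lVert s_i-s_j\rVert}$, nugget $\epsilon_i \sim N(0,\tau^2)$ |
| car | $y \sim N(X\beta,\ \tau^2 (D_M - \phi M)^{-1})$ on the plot adjacency graph $M$ |

Bands are selected by PIP ≥ 0.6 or by the most probable submodel (*avgmod*);
predictive power is measured by repeated-holdout cross-validation (25 of 126
plots held out, 5 repeats) with model-based spatial prediction of the held-out
plots, and benchmarked against five classical vegetation indices (SR, NDVI,
GNDVI, SAVI, OSAVI). A synthetic-trial generator emulates a 126-plot
split-plot phosphorus experiment (2 fertilization levels × 21 genotypes × 3
replicates) so the entire pipeline runs with no external data. The methods
vignette (`vignettes/band-selection-methods.Rmd`) documents the priors,
numerical choices and limitations.

## Worked example

Simulate an emulated trial, preprocess, fit the CAR model, and summarize.
The fit uses the moderate inclusion prior `p0 = 0.5` (prior indifference per
band), which suits spectra whose neighboring bands share the signal; the
sparser package default (`p0 = 0.9`) targets settings with few informative
predictors (see the vignette for the trade-off).

```r
library(specar)

trial <- simulate_field_trial(emulation_config(seed = 1, raw_step = 2))
spectra <- resample_bsplines(filter_window(trial$raw, 450, 850))
ds <- assemble_dataset(spectra, trial$pheno)
ds
#> regression_dataset: n = 126 plots, p = 101 bands

pr <- list(beta = spike_slab_prior(p0 = 0.5), tau2 = variance_prior(),
           phi = phi_prior(trial$fs$phi_support[1], trial$fs$phi_support[2]))
fit <- fit_model(ds$y, ds$X, "car", fs = trial$fs, priors = pr,
                 cfg = mcmc_config(n_iter = 10000, burn_in = 5000, thin = 5,
                                   seed = 2))
fit
#> posterior_samples (car): 1000 kept draws, p = 101 bands
#>   mean model size: 20.9 bands
#>   E[tau2   | data] = 0.05283
#>   E[phi    | data] = 0.4064  (MH acceptance 37%)

fit_summary(fit)
#> DIC = -147.05 ( Dbar = -169.57 , p_D = 22.52 )

sel <- selection_summary(fit, threshold = 0.6)
sel
#> selection_summary: 10 of 101 bands with PIP >= 0.6 ; avgmod has 19 bands (posterior frequency 0.002 )
spectra$band_centers[sel$selected_threshold]
#>  [1] 538 546 634 666 670 766 782 786 834 838
```

The fitted CAR variance `E[tau2 | data]` ≈ 0.053 matches the generator's
spatial-field variance (0.05), and the positive posterior mean of `phi`
recovers the planted positive neighbor dependence. Six of the ten selected
bands (538–670 nm) fall in the 500–690 nm region the generator wires to
grain phosphorus; the near-infrared stragglers ride on chance correlations
at n = 126 — the PIP profile, not just the thresholded set, is the thing to
read.

Cross-validated predictive correlation against a vegetation-index baseline
(defaults throughout):

```r
splits <- cv_split(ds$n, n_test = 25, repeats = 5, seed = 3)
cv <- cross_validate(ds, "car", fs = trial$fs, splits = splits,
                     cfg = mcmc_config(n_iter = 4000, burn_in = 2000,
                                       thin = 2, seed = 4))
cv
#> cv_report (car): per-repeat r = 0.729, 0.644, 0.795, 0.814, 0.596; mean r = 0.716

ndvi <- compute_index(veg_indices()$NDVI, spectra)
index_cv_correlations(ndvi, ds$y, splits)$mean_r
#> [1] 0.4042626
```

The CAR model predicts held-out plots much better than NDVI here (mean r
0.72 vs 0.40) because it uses the full selected-band signal *and* borrows
strength from the held-out plots' neighbors. `run_pipeline()` assembles all
of the above — three models × three band-selection criteria, DIC and CV
tables, index comparison — into one report.

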