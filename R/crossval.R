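#' Repeated random train/test splits
#'
#' Per repeat, a uniformly random test subset of size `n_test` drawn
#' without replacement; the training set is its complement.  Reproducible
#' from `seed`.
#'
#' @param n number of observations.
#' @param n_test test-set size (0 < `n_test` < `n`); the study design uses
#'   25 test / 101 training plots out of 126.
#' @param repeats number of repeats (default 5).
#' @param seed RNG seed.
#' @return List of `repeats` elements, each `list(test = ..., train = ...)`
#'   of integer row indices.
#' @export
cv_split <- function(n, n_test = 25, repeats = 5, seed = 1) {
  if (n_test <= 0 || n_test >= n)
    stop("n_test must satisfy 0 < n_test < n")
  set.seed(seed)
  lapply(seq_len(repeats), function(i) {
    test <- sort(sample.int(n, n_test))
    list(test = test, train = setdiff(seq_len(n), test))
  })
}

#' Predict held-out plots from a training fit
#'
#' Plug-in predictions at the posterior means of the training fit:
#' * independent: `X_test beta_hat`;
#' * geostatistical: adds `E[w_test | w_hat_train]` under the exponential
#'   correlogram at the posterior-mean `phi_hat` (simple kriging of the
#'   posterior-mean latent field onto the held-out sites);
#' * CAR: adds the conditional mean of the held-out block of the joint CAR
#'   distribution given the training residuals, computed from the
#'   partitioned full-field precision `(D_M - phi_hat M)` (never an
#'   explicit full inverse).
#'
#' @param samples `posterior_samples` fitted on the training rows only.
#' @param dataset the full `regression_dataset` (or list with `y`, `X`).
#' @param fs the full-field `field_structure` (spatial kinds).
#' @param train,test integer row indices; `train` must match the rows the
#'   model was fitted on, in the same order.
#' @return Numeric vector of predictions for the `test` rows.
#' @export
predict_heldout <- function(samples, dataset, fs = NULL, train, test) {
  y <- dataset$y; X <- dataset$X
  if (samples$n != length(train))
    stop("fit used ", samples$n, " rows but train has ", length(train))
  if (!is.null(fs) && length(intersect(test, seq_len(fs$n))) != length(test))
    stop("test plot(s) absent from the field structure")
  bm <- samples$post_mean
  mu_test <- unname(bm$intercept + drop(X[test, , drop = FALSE] %*% bm$beta))
  if (samples$kind == "independent") return(mu_test)
  if (samples$kind == "geospatial") {
    D <- as.matrix(stats::dist(fs$coords))
    H11 <- exp(-bm$phi * D[train, train, drop = FALSE])
    H21 <- exp(-bm$phi * D[test, train, drop = FALSE])
    w_test <- drop(H21 %*% solve(H11, bm$w))
    return(mu_test + unname(w_test))
  }
  # CAR: E[y_te | y_tr] = mu_te - Q22^{-1} Q21 (y_tr - mu_tr)
  Q <- diag(fs$d_m) - bm$phi * fs$M
  mu_train <- bm$intercept + drop(X[train, , drop = FALSE] %*% bm$beta)
  r_train <- y[train] - mu_train
  Q21 <- Q[test, train, drop = FALSE]
  Q22 <- Q[test, test, drop = FALSE]
  mu_test - unname(drop(solve(Q22, Q21 %*% r_train)))
}

#' Cross-validated predictive correlation of a model
#'
#' For each split, refits the model on the training rows only (for the CAR
#' kind the training-only likelihood uses the field precision restricted to
#' the training plots, a valid Gaussian in its own right), predicts the
#' held-out plots with [predict_heldout()], and records the Pearson
#' correlation between predictions and observed responses.
#'
#' @param dataset a `regression_dataset` (or list with `y`, `X`).
#' @param kind model kind, as in [fit_model()].
#' @param fs full-field `field_structure` (spatial kinds).
#' @param splits list from [cv_split()].
#' @param priors,cfg passed to [fit_model()]; per-repeat seeds are derived
#'   from `cfg$seed`.
#' @param selection passed to [fit_model()] (disable when evaluating a
#'   fixed band set).
#' @return A `cv_report`: list with per-repeat records (`test`,
#'   `predictions`, `r`) and `mean_r`.
#' @export
cross_validate <- function(dataset, kind, fs = NULL, splits,
                           priors = NULL, cfg = mcmc_config(),
                           selection = TRUE) {
  reps <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    fs_tr <- if (kind == "independent") NULL else subset_field(fs, sp$train)
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    fit <- fit_model(dataset$y[sp$train],
                     dataset$X[sp$train, , drop = FALSE],
                     kind = kind, fs = fs_tr, priors = priors, cfg = cfg_i,
                     selection = selection)
    # held-out prediction needs the training fit plus the full field
    fit_for_pred <- fit
    pred <- predict_heldout(fit_for_pred, dataset, fs = fs,
                            train = sp$train, test = sp$test)
    reps[[i]] <- list(test = sp$test, predictions = pred,
                      r = cor(dataset$y[sp$test], pred))
  }
  rs <- vapply(reps, `[[`, numeric(1), "r")
  structure(list(repeats = reps, r = rs, mean_r = mean(rs), kind = kind),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report (", x$kind, "): per-repeat r = ",
      paste(round(x$r, 3), collapse = ", "),
      "; mean r = ", round(x$mean_r, 3), "\n", sep = "")
  invisible(x)
}

#' Percentage-point gap between the CAR model and the index baselines
#'
#' `100 * (car_mean_r - mean(index_rs))`: how much the CAR model's average
#' cross-validated correlation exceeds the average of the vegetation-index
#' correlations, in percentage points.
#'
#' @param car_mean_r mean cross-validated correlation of the CAR model.
#' @param index_rs vector of per-index mean correlations.
#' @return The difference in percentage points.
#' @export
compare_to_indices <- function(car_mean_r, index_rs) {
  stopifnot(all(abs(c(car_mean_r, index_rs)) <= 1))
  100 * (car_mean_r - mean(index_rs))
}
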