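# FNV-1a hash of a deparsed object; used to stamp report files so a rerun
# with an identical configuration is recognizably the same analysis.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- bitwAnd(bitwXor(h, b) * 16777619, 0xFFFFFFFF)
  sprintf("%08x", h)
}

#' Run the full band-selection analysis pipeline
#'
#' Orchestrates, per year: spectral preprocessing (window, B-spline
#' resampling to the 4 nm grid), fitting the three model kinds with
#' spike-and-slab selection, band selection under the two criteria (PIP
#' threshold and most-probable submodel), DIC for each model-by-criterion
#' cell (restricted cells are refitted on the selected bands with selection
#' disabled), repeated-holdout cross-validation for every cell, the five
#' vegetation-index baselines on the same splits, and the percentage-point
#' comparison of the CAR model against the index average.
#'
#' @param raw a `raw_spectra` table, or `NULL` to emulate a trial.
#' @param pheno a `phenotype` table (required with `raw`).
#' @param fs `field_structure`; defaults to the standard 21 x 6 layout.
#' @param emu_cfg [emulation_config()] used when `raw` is `NULL`.
#' @param window wavelength window in nm.
#' @param band_step resampling bandwidth in nm.
#' @param kinds model kinds to fit.
#' @param mcmc an [mcmc_config()]; its seed drives every fit.
#' @param n_test,repeats cross-validation geometry (25 test / 5 repeats).
#' @param threshold PIP selection threshold.
#' @param out_dir if non-`NULL`, CSV tables and a JSON summary (stamped
#'   with the configuration hash and seed) are written there.
#' @return An `evaluation_report`: list with `dic` and `cv` tables (model x
#'   criterion x year), `index_table`, `index_comparison`, per-model
#'   `selection` summaries, `diagnostics`, and the `config_hash`.
#' @export
run_pipeline <- function(raw = NULL, pheno = NULL, fs = NULL,
                         emu_cfg = emulation_config(),
                         window = c(450, 850), band_step = 4,
                         kinds = c("independent", "geospatial", "car"),
                         mcmc = mcmc_config(), n_test = 25, repeats = 5,
                         threshold = 0.6, out_dir = NULL) {
  call_cfg <- list(window = window, band_step = band_step, kinds = kinds,
                   mcmc = unclass(mcmc), n_test = n_test, repeats = repeats,
                   threshold = threshold,
                   emulated = is.null(raw))
  if (is.null(raw)) {
    trial <- simulate_field_trial(emu_cfg)
    raw <- trial$raw; pheno <- trial$pheno; fs <- trial$fs
    call_cfg$emu_cfg <- unclass(emu_cfg)
  } else if (is.null(pheno)) {
    stop("pheno is required when raw spectra are supplied")
  }
  hash <- config_hash(call_cfg)

  ctr <- band_grid(window[1], window[2], band_step)
  crits <- c("all_bands", "pip_0.6", "avgmod")
  dic_rows <- list(); cv_rows <- list(); idx_rows <- list()
  cmp_rows <- list(); selections <- list(); diags <- list()

  for (yr in sort(unique(pheno$year))) {
    ph_y <- pheno[pheno$year == yr, , drop = FALSE]
    raw_y <- raw[raw$plot_id %in% ph_y$plot_id, , drop = FALSE]
    class(raw_y) <- class(raw)
    win <- filter_window(raw_y, window[1], window[2])
    spectra <- resample_bsplines(win, ctr)
    ds <- assemble_dataset(spectra, ph_y)
    if (is.null(fs)) fs <- build_layout(n_rows = ceiling(ds$n / 6),
                                        n_plots = ds$n)
    if (fs$n != ds$n) stop("field structure (", fs$n,
                           " plots) does not match year ", yr,
                           " (", ds$n, " plots)")
    splits <- cv_split(ds$n, n_test = n_test, repeats = repeats,
                       seed = mcmc$seed)

    cell_r <- list()
    for (kind in kinds) {
      fs_k <- if (kind == "independent") NULL else fs
      full <- fit_model(ds$y, ds$X, kind = kind, fs = fs_k, cfg = mcmc)
      sel <- selection_summary(full, threshold = threshold)
      selections[[paste(yr, kind, sep = "_")]] <- sel
      diags[[paste(yr, kind, sep = "_")]] <- fit_diagnostics(full)
      band_sets <- list(all_bands = seq_len(ds$p),
                        `pip_0.6` = sel$selected_threshold,
                        avgmod = which(sel$avgmod == 1))
      for (crit in crits) {
        bands <- band_sets[[crit]]
        if (length(bands) == 0) {
          warning(kind, " / ", crit, " (", yr, "): empty band set, skipped")
          dic_val <- NA_real_; mean_r <- NA_real_
        } else {
          if (crit == "all_bands") {
            dic_val <- fit_summary(full)$dic
            sel_flag <- TRUE
          } else {
            refit <- fit_model(ds$y, ds$X[, bands, drop = FALSE],
                               kind = kind, fs = fs_k, cfg = mcmc,
                               selection = FALSE)
            dic_val <- fit_summary(refit)$dic
            sel_flag <- FALSE
          }
          ds_crit <- list(y = ds$y, X = ds$X[, bands, drop = FALSE])
          cvr <- cross_validate(ds_crit, kind = kind, fs = fs_k,
                                splits = splits, cfg = mcmc,
                                selection = sel_flag)
          mean_r <- cvr$mean_r
        }
        dic_rows[[length(dic_rows) + 1L]] <-
          data.frame(year = yr, model = kind, criterion = crit,
                     dic = dic_val, stringsAsFactors = FALSE)
        cv_rows[[length(cv_rows) + 1L]] <-
          data.frame(year = yr, model = kind, criterion = crit,
                     mean_r = mean_r, stringsAsFactors = FALSE)
        cell_r[[paste(kind, crit, sep = ".")]] <- mean_r
      }
    }

    idx_defs <- veg_indices()
    idx_r <- vapply(idx_defs, function(ix) {
      v <- compute_index(ix, spectra)
      index_cv_correlations(v, ds$y, splits)$mean_r
    }, numeric(1))
    for (nmx in names(idx_r))
      idx_rows[[length(idx_rows) + 1L]] <-
        data.frame(year = yr, index = nmx, mean_r = idx_r[[nmx]],
                   stringsAsFactors = FALSE)
    car_r <- cell_r[["car.avgmod"]]
    if (!is.null(car_r) && is.finite(car_r))
      cmp_rows[[length(cmp_rows) + 1L]] <-
        data.frame(year = yr, car_mean_r = car_r,
                   index_mean_r = mean(idx_r),
                   delta_pct = compare_to_indices(car_r, unname(idx_r)),
                   stringsAsFactors = FALSE)
  }

  report <- structure(list(
    dic = do.call(rbind, dic_rows),
    cv = do.call(rbind, cv_rows),
    index_table = do.call(rbind, idx_rows),
    index_comparison = if (length(cmp_rows)) do.call(rbind, cmp_rows),
    selection = selections, diagnostics = diags,
    config = call_cfg, config_hash = hash, seed = mcmc$seed),
    class = "evaluation_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- function(df) { df$config_hash <- hash; df$seed <- mcmc$seed; df }
    write.csv(stamp(report$dic), file.path(out_dir, "dic_table.csv"),
              row.names = FALSE)
    write.csv(stamp(report$cv), file.path(out_dir, "cv_table.csv"),
              row.names = FALSE)
    write.csv(stamp(report$index_table),
              file.path(out_dir, "index_table.csv"), row.names = FALSE)
    if (!is.null(report$index_comparison))
      write.csv(stamp(report$index_comparison),
                file.path(out_dir, "index_comparison.csv"),
                row.names = FALSE)
    pips <- do.call(rbind, lapply(names(selections), function(k)
      data.frame(cell = k, band = names(selections[[k]]$pip),
                 pip = unname(selections[[k]]$pip),
                 stringsAsFactors = FALSE)))
    write.csv(stamp(pips), file.path(out_dir, "pip_table.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(config = call_cfg, config_hash = hash, seed = mcmc$seed,
           diagnostics = diags),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

# Convergence diagnostics for the scalar parameters of a fit: split R-hat
# and effective sample size; R-hat > 1.05 raises a warning (diagnostic
# only, never a gate).
fit_diagnostics <- function(samples) {
  sc <- list(deviance = samples$deviance)
  if (!is.null(samples$sigma2)) sc$sigma2 <- samples$sigma2
  if (!is.null(samples$tau2)) sc$tau2 <- samples$tau2
  if (!is.null(samples$phi)) sc$phi <- samples$phi
  out <- lapply(sc, function(x)
    list(rhat = split_rhat(x), ess = effective_size(x)))
  bad <- names(out)[vapply(out, function(d) d$rhat > 1.05, logical(1))]
  if (length(bad))
    warning("split R-hat > 1.05 for: ", paste(bad, collapse = ", "),
            " (consider longer chains)")
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (config", x$config_hash, ", seed", x$seed, ")\n")
  cat("\nDIC (model x criterion x year):\n")
  print(x$dic, row.names = FALSE)
  cat("\nMean CV correlation:\n")
  print(x$cv, row.names = FALSE)
  cat("\nVegetation indices:\n")
  print(x$index_table, row.names = FALSE)
  if (!is.null(x$index_comparison)) {
    cat("\nCAR vs index average (percentage points):\n")
    print(x$index_comparison, row.names = FALSE)
  }
  invisible(x)
}
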