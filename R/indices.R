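#' Built-in vegetation index definitions
#'
#' The five classical baselines, as tabulated in the nutrient-monitoring
#' literature.  Range subscripts (e.g. `R_800-900`) denote the mean
#' reflectance over the bands inside the range; single subscripts
#' (`R_800`) the nearest band center.  `SAVI` and `OSAVI` are, by default,
#' in the form with the leading constant (1.5 / 1.16) on the first
#' numerator term only; `canonical = TRUE` switches to the textbook forms
#' in which the constant multiplies the whole difference.
#'
#' @param canonical use the canonical SAVI/OSAVI formulas.
#' @return Named list of `veg_index_spec` objects (`SR`, `NDVI`, `GNDVI`,
#'   `SAVI`, `OSAVI`), each with a `compute(spectra)` function.
#' @export
veg_indices <- function(canonical = FALSE) {
  mk <- function(name, f) structure(list(name = name, compute = f),
                                    class = "veg_index_spec")
  list(
    SR = mk("SR", function(sp)
      band_mean(sp, 800, 900) / band_mean(sp, 650, 700)),
    NDVI = mk("NDVI", function(sp) {
      a <- band_mean(sp, 800, 800); b <- band_mean(sp, 680, 680)
      (a - b) / (a + b)
    }),
    GNDVI = mk("GNDVI", function(sp) {
      a <- band_mean(sp, 800, 900); b <- band_mean(sp, 540, 560)
      (a - b) / (a + b)
    }),
    SAVI = mk("SAVI", if (canonical) function(sp) {
      a <- band_mean(sp, 800, 900); b <- band_mean(sp, 650, 700)
      1.5 * (a - b) / (a + b + 0.5)
    } else function(sp) {
      a <- band_mean(sp, 800, 900); b <- band_mean(sp, 650, 700)
      (1.5 * a - b) / (a + b + 0.5)
    }),
    OSAVI = mk("OSAVI", if (canonical) function(sp) {
      a <- band_mean(sp, 800, 800); b <- band_mean(sp, 670, 670)
      1.16 * (a - b) / (a + b + 0.16)
    } else function(sp) {
      a <- band_mean(sp, 800, 800); b <- band_mean(sp, 670, 670)
      (1.16 * a - b) / (a + b + 0.16)
    })
  )
}

#' Mean reflectance over a wavelength range
#'
#' Averages the resampled bands whose centers fall in `[lo, hi]`.  Ranges
#' reaching past the available grid are truncated to it (the common case is
#' `R_800-900` truncated to 800--850 nm on a 450--850 nm grid); a point
#' query (`lo == hi`) maps to the nearest band center, ties resolved to the
#' lower center.
#'
#' @param spectra a `resampled_spectra` object.
#' @param lo,hi range bounds in nm (`lo == hi` for a single wavelength).
#' @return Named per-plot vector of mean reflectance.
#' @export
band_mean <- function(spectra, lo, hi = lo) {
  ctr <- spectra$band_centers
  if (lo == hi) {
    d <- abs(ctr - lo)
    j <- which(d == min(d))
    j <- j[which.min(ctr[j])]   # tie -> lower center
    return(spectra$X[, j])
  }
  keep <- ctr >= lo & ctr <= hi
  if (!any(keep))
    stop("range [", lo, ", ", hi, "] nm does not intersect the band grid [",
         min(ctr), ", ", max(ctr), "]")
  rowMeans(spectra$X[, keep, drop = FALSE])
}

#' Compute a vegetation index for every plot
#'
#' Plots with a zero denominator get `NA` with a warning.
#'
#' @param spec a `veg_index_spec` from [veg_indices()].
#' @param spectra a `resampled_spectra` object.
#' @return Named per-plot vector of index values.
#' @export
compute_index <- function(spec, spectra) {
  v <- spec$compute(spectra)
  bad <- !is.finite(v)
  if (any(bad)) {
    warning(spec$name, ": undefined (zero denominator) for plot(s) ",
            paste(spectra$plot_id[bad], collapse = ", "))
    v[bad] <- NA_real_
  }
  v
}

#' Cross-validated correlation of a vegetation index
#'
#' Uses the *same* splits as the model cross-validation: per repeat, the
#' Pearson correlation between the index and the log response over the test
#' plots; the mean over repeats is reported.  A repeat on which the index
#' is constant (undefined correlation) is dropped from the mean with a
#' warning.
#'
#' @param index per-plot index values (aligned with `y`).
#' @param y per-plot log response.
#' @param splits list from [cv_split()].
#' @return List with per-repeat `r` and `mean_r`.
#' @export
index_cv_correlations <- function(index, y, splits) {
  rs <- vapply(splits, function(sp) {
    xi <- index[sp$test]; yi <- y[sp$test]
    ok <- is.finite(xi) & is.finite(yi)
    if (sum(ok) < 3 || sd(xi[ok]) == 0 || sd(yi[ok]) == 0) return(NA_real_)
    cor(xi[ok], yi[ok])
  }, numeric(1))
  if (anyNA(rs))
    warning(sum(is.na(rs)), " repeat(s) with undefined correlation excluded")
  list(r = rs, mean_r = mean(rs, na.rm = TRUE))
}
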