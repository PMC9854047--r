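#' Read a raw spectra table from CSV
#'
#' Accepts either the long layout (columns `plot_id`, `wavelength_nm`,
#' `reflectance`) or the wide layout (first column `plot_id`, remaining
#' columns named by wavelength in nm).  The layout is auto-detected from the
#' header.  Whatever wavelength grid the file carries is accepted as-is.
#'
#' @param path path to a CSV file.
#' @return A `raw_spectra` object: a long-format data frame with columns
#'   `plot_id`, `wavelength`, `reflectance` (possibly `NA`), sorted by plot
#'   then wavelength.
#' @export
read_spectra <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  if (all(c("plot_id", "wavelength_nm", "reflectance") %in% nm)) {
    out <- data.frame(plot_id = as.character(df$plot_id),
                      wavelength = as.numeric(df$wavelength_nm),
                      reflectance = as.numeric(df$reflectance),
                      stringsAsFactors = FALSE)
  } else {
    wl <- suppressWarnings(as.numeric(nm[-1]))
    if (anyNA(wl))
      stop("cannot auto-detect spectra layout: non-numeric wavelength columns ",
           paste(nm[-1][is.na(wl)][1:min(3, sum(is.na(wl)))], collapse = ", "))
    out <- data.frame(
      plot_id = rep(as.character(df[[1]]), times = length(wl)),
      wavelength = rep(wl, each = nrow(df)),
      reflectance = as.numeric(unlist(df[-1], use.names = FALSE)),
      stringsAsFactors = FALSE)
  }
  as_raw_spectra(out)
}

#' Construct a raw spectra table
#'
#' Validates and orders a long-format table of per-plot reflectance spectra.
#'
#' @param df data frame with columns `plot_id`, `wavelength` (nm),
#'   `reflectance` (unitless fraction, may be `NA`).
#' @return A `raw_spectra` data frame sorted by plot then wavelength.
#' @export
as_raw_spectra <- function(df) {
  stopifnot(all(c("plot_id", "wavelength", "reflectance") %in% names(df)))
  df <- df[order(df$plot_id, df$wavelength), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df[c("plot_id", "wavelength")]))
    stop("duplicate (plot_id, wavelength) rows: one spectrum per plot required")
  fin <- df$reflectance[!is.na(df$reflectance)]
  if (any(!is.finite(fin)))
    stop("non-finite reflectance values present")
  class(df) <- c("raw_spectra", "data.frame")
  df
}

#' Restrict spectra to a wavelength window
#'
#' Keeps only wavelengths inside `[lo, hi]` (bounds included).  The plot set
#' is unchanged; a plot left with no rows raises an error naming it.
#'
#' @param raw a `raw_spectra` table.
#' @param lo,hi window bounds in nm, `lo < hi`.
#' @return A `raw_spectra` table restricted to the window.
#' @export
filter_window <- function(raw, lo = 450, hi = 850) {
  stopifnot(lo < hi)
  plots_before <- unique(raw$plot_id)
  out <- raw[raw$wavelength >= lo & raw$wavelength <= hi, , drop = FALSE]
  gone <- setdiff(plots_before, unique(out$plot_id))
  if (length(gone))
    stop("window [", lo, ", ", hi, "] nm leaves no data for plot(s): ",
         paste(gone, collapse = ", "))
  rownames(out) <- NULL
  class(out) <- c("raw_spectra", "data.frame")
  out
}

#' Band centers of a uniform grid
#'
#' @param lo,hi grid end points in nm.
#' @param step band width in nm.
#' @return Numeric vector `lo, lo+step, ..., hi`; for (450, 850, 4) this has
#'   exactly 101 elements.
#' @export
band_grid <- function(lo = 450, hi = 850, step = 4) seq(lo, hi, by = step)

# Penalized cubic B-spline smoother with GCV.
#
# P-spline construction: cubic B-spline basis on equally spaced interior
# knots, second-order difference penalty on the coefficients, smoothing
# parameter chosen by minimizing GCV(lambda) = n RSS / (n - tr S)^2 over a
# log-spaced grid whose lower endpoint is effectively zero, so noiseless
# data (polynomials in particular) are reproduced to near machine precision.
fit_pspline <- function(x, y, nknots = NULL, lambda = NULL) {
  n <- length(x)
  if (is.null(nknots)) nknots <- max(4, min(100, floor(n / 4)))
  degree <- 3
  rng <- range(x)
  inner <- seq(rng[1], rng[2], length.out = nknots)
  knots <- c(rep(rng[1], degree), inner, rep(rng[2], degree))
  B <- splines::splineDesign(knots, x, ord = degree + 1)
  k <- ncol(B)
  D2 <- diff(diag(k), differences = 2)
  P <- crossprod(D2)
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)
  yty <- sum(y^2)
  scale <- sum(diag(BtB)) / sum(diag(P))
  gcv_at <- function(lam) {
    A <- BtB + lam * P
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(list(gcv = Inf))
    theta <- backsolve(R, backsolve(R, Bty, transpose = TRUE))
    # tr S = tr((B'B + lam P)^-1 B'B)
    Ainv_BtB <- backsolve(R, backsolve(R, BtB, transpose = TRUE))
    trS <- sum(diag(Ainv_BtB))
    rss <- max(yty - 2 * sum(theta * Bty) + sum(theta * (BtB %*% theta)), 0)
    denom <- max(n - trS, 1e-8)
    list(gcv = n * rss / denom^2, theta = theta)
  }
  if (is.null(lambda)) {
    grid <- scale * 10^seq(-12, 8, length.out = 41)
    gcvs <- vapply(grid, function(l) gcv_at(l)$gcv, numeric(1))
    lambda <- grid[which.min(gcvs)]
  }
  fit <- gcv_at(lambda)
  if (!is.finite(fit$gcv)) stop("penalized spline system is singular")
  structure(list(knots = knots, degree = degree, theta = fit$theta,
                 lambda = lambda, range = rng), class = "pspline_fit")
}

predict_pspline <- function(fit, xnew) {
  Bn <- splines::splineDesign(fit$knots, xnew, ord = fit$degree + 1)
  drop(Bn %*% fit$theta)
}

#' Resample spectra onto a coarse band grid with penalized B-splines
#'
#' Fits, per plot, a cubic penalized B-spline (smoothing chosen by
#' generalized cross-validation unless `lambda` is given) to the non-missing
#' (wavelength, reflectance) pairs and evaluates it at `band_centers`.
#' Missing raw bands are simply dropped before fitting; requesting centers
#' outside a plot's observed range is an error (no extrapolation), except
#' that centers within `extrap_tol` nm of the boundary are evaluated at the
#' boundary itself (a windowed raw grid rarely contains the window
#' endpoints exactly; a sub-bandwidth clamp is harmless for smooth
#' spectra).
#' Resampled reflectance is clamped to `[0, 1.5]` (white-reference-calibrated
#' values can mildly exceed 1); clamped plots are reported via a warning.
#'
#' @param raw a `raw_spectra` table (typically already windowed with
#'   [filter_window()]).
#' @param band_centers target band centers in nm; defaults to the
#'   450--850 nm grid at 4 nm (101 bands).
#' @param nknots number of interior knots for the spline basis.
#' @param lambda optional fixed smoothing parameter (bypasses GCV).
#' @param extrap_tol boundary clamp tolerance in nm.
#' @return A `resampled_spectra` object: list with `plot_id`,
#'   `band_centers`, and the plot-by-band matrix `X` (no missing values).
#' @export
resample_bsplines <- function(raw, band_centers = band_grid(),
                              nknots = NULL, lambda = NULL,
                              extrap_tol = 2) {
  plots <- unique(raw$plot_id)
  X <- matrix(NA_real_, length(plots), length(band_centers),
              dimnames = list(plots, paste0("b", band_centers)))
  clamped <- character(0)
  for (pl in plots) {
    sub <- raw[raw$plot_id == pl & !is.na(raw$reflectance), , drop = FALSE]
    if (nrow(sub) < 5)
      stop("plot ", pl, ": only ", nrow(sub),
           " non-missing points; too few for a cubic spline fit")
    rng <- range(sub$wavelength)
    if (min(band_centers) < rng[1] - extrap_tol ||
        max(band_centers) > rng[2] + extrap_tol)
      stop("plot ", pl, ": band centers outside observed range [",
           round(rng[1], 2), ", ", round(rng[2], 2),
           "] nm; extrapolation refused")
    fit <- fit_pspline(sub$wavelength, sub$reflectance,
                       nknots = nknots, lambda = lambda)
    v <- predict_pspline(fit, pmin(pmax(band_centers, rng[1]), rng[2]))
    if (any(v < 0 | v > 1.5)) clamped <- c(clamped, pl)
    X[pl, ] <- pmin(pmax(v, 0), 1.5)
  }
  if (length(clamped))
    warning("reflectance clamped to [0, 1.5] for plot(s): ",
            paste(clamped, collapse = ", "))
  structure(list(plot_id = plots, band_centers = band_centers, X = X),
            class = "resampled_spectra")
}

#' @export
print.resampled_spectra <- function(x, ...) {
  cat("resampled_spectra:", nrow(x$X), "plots x", ncol(x$X), "bands (",
      min(x$band_centers), "-", max(x$band_centers), "nm )\n")
  invisible(x)
}

#' Write resampled spectra as a wide CSV
#'
#' First column `plot_id`, remaining columns one per band center (nm).
#'
#' @param spectra a `resampled_spectra` object.
#' @param path output CSV path.
#' @export
write_resampled_spectra <- function(spectra, path) {
  df <- data.frame(plot_id = spectra$plot_id, spectra$X,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("plot_id", spectra$band_centers)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with headers `plot_id`, `year`, `genotype`, `p_level`, `rep`,
#' `grain_p`.  The log response `y = ln(grain_p)` is added.
#'
#' @param path CSV path.
#' @return A `phenotype` data frame with the extra column `y`.
#' @export
read_phenotype <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_phenotype(df)
}

#' Construct a phenotype table
#'
#' @param df data frame with columns `plot_id`, `year`, `genotype`,
#'   `p_level`, `rep`, `grain_p` (> 0).
#' @return A `phenotype` data frame with `y = log(grain_p)` appended.
#' @export
as_phenotype <- function(df) {
  need <- c("plot_id", "year", "genotype", "p_level", "rep", "grain_p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$grain_p <= 0)) stop("grain_p must be strictly positive")
  df$plot_id <- as.character(df$plot_id)
  df$y <- log(df$grain_p)
  class(df) <- c("phenotype", "data.frame")
  df
}

#' Assemble the regression dataset
#'
#' Joins resampled spectra with the phenotype table by `plot_id`.  Row order
#' follows the spectra's plot order (the field-layout ordering), so the rows
#' of `X` and the entries of `y` always align with the field structure.
#'
#' @param spectra a `resampled_spectra` object.
#' @param pheno a `phenotype` table; plot ids must match one-to-one.
#' @return A `regression_dataset`: list with `y` (log grain phosphorus), `X`
#'   (plot-by-band reflectance), `plot_id`, `pheno`, and sizes `n`, `p`.
#' @export
assemble_dataset <- function(spectra, pheno) {
  sp <- spectra$plot_id
  ph <- pheno$plot_id
  only_s <- setdiff(sp, ph)
  only_p <- setdiff(ph, sp)
  if (length(only_s) || length(only_p))
    stop("plot ids do not match one-to-one; spectra-only: {",
         paste(only_s, collapse = ", "), "}, phenotype-only: {",
         paste(only_p, collapse = ", "), "}")
  idx <- match(sp, ph)
  y <- pheno$y[idx]
  structure(list(y = y, X = spectra$X, plot_id = sp,
                 band_centers = spectra$band_centers,
                 pheno = pheno[idx, , drop = FALSE],
                 n = length(y), p = ncol(spectra$X)),
            class = "regression_dataset")
}

#' @export
print.regression_dataset <- function(x, ...) {
  cat("regression_dataset: n =", x$n, "plots, p =", x$p, "bands\n")
  invisible(x)
}
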