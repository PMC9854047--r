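test_that("filter_window keeps boundary wavelengths and is idempotent", {
  raw <- as_raw_spectra(data.frame(
    plot_id = "P01", wavelength = c(440, 450, 650, 850, 860),
    reflectance = c(0.1, 0.2, 0.3, 0.4, 0.5)))
  win <- filter_window(raw, 450, 850)
  expect_equal(win$wavelength, c(450, 650, 850))

  # window equal to full range is the identity
  full <- filter_window(raw, 440, 860)
  expect_equal(full$wavelength, raw$wavelength)
  expect_equal(full$reflectance, raw$reflectance)

  # idempotence
  expect_equal(filter_window(win, 450, 850), win)
})

test_that("filter_window errors when a plot is emptied, keeps plot set otherwise", {
  raw <- toy_raw_spectra(n_plots = 3)
  win <- filter_window(raw, 450, 850)
  expect_setequal(unique(win$plot_id), unique(raw$plot_id))
  expect_true(all(win$wavelength >= 450 & win$wavelength <= 850))

  two <- as_raw_spectra(data.frame(
    plot_id = c("A", "A", "B"), wavelength = c(500, 600, 900),
    reflectance = 0.2))
  expect_error(filter_window(two, 450, 850), "B")
})

test_that("resampling yields the full 4 nm grid and reproduces simple spectra", {
  expect_length(band_grid(450, 850, 4), 101)

  raw <- toy_raw_spectra(n_plots = 2, step = 1)
  win <- filter_window(raw, 450, 850)
  rs <- resample_bsplines(win)
  expect_equal(ncol(rs$X), 101)
  expect_equal(rs$band_centers, seq(450, 850, by = 4))
  expect_false(anyNA(rs$X))

  # constant spectrum is reproduced exactly at every center
  wl <- seq(450, 850, by = 1)
  const <- as_raw_spectra(data.frame(plot_id = "C", wavelength = wl,
                                     reflectance = 0.5))
  expect_equal(unname(resample_bsplines(const)$X[1, ]), rep(0.5, 101),
               tolerance = 1e-9)

  # linear ramp: oracle is the ramp itself at the centers
  a <- 0.05; b <- 4e-4
  ramp <- as_raw_spectra(data.frame(plot_id = "L", wavelength = wl,
                                    reflectance = a + b * wl))
  got <- unname(resample_bsplines(ramp)$X[1, ])
  expect_equal(got, a + b * seq(450, 850, 4), tolerance = 1e-8)
})

test_that("polynomials up to the spline degree are reproduced to 1e-8 relative", {
  wl <- seq(450, 850, by = 0.5)
  f <- function(l) 0.2 + 1e-4 * (l - 650) + 2e-6 * (l - 650)^2 -
    1e-9 * (l - 650)^3
  cub <- as_raw_spectra(data.frame(plot_id = "Q", wavelength = wl,
                                   reflectance = f(wl)))
  ctr <- band_grid()
  got <- unname(resample_bsplines(cub)$X[1, ])
  expect_lt(max(abs(got - f(ctr)) / abs(f(ctr))), 1e-8)
})

test_that("resampling smooths noise and honours missingness", {
  wl <- seq(450, 850, by = 1)
  truth <- 0.3 + 0.2 * exp(-(wl - 650)^2 / (2 * 60^2))
  set.seed(3)
  r <- truth + rnorm(length(wl), 0, 0.02)
  r[sample(length(wl), 40)] <- NA   # scattered missingness is dropped
  raw <- as_raw_spectra(data.frame(plot_id = "N", wavelength = wl,
                                   reflectance = r))
  got <- unname(resample_bsplines(raw)$X[1, ])
  truth_c <- 0.3 + 0.2 * exp(-(band_grid() - 650)^2 / (2 * 60^2))
  # smoothing beats the raw noise level
  expect_lt(sd(got - truth_c), 0.01)
})

test_that("resampling refuses extrapolation and too-few points", {
  short <- as_raw_spectra(data.frame(plot_id = "S",
                                     wavelength = seq(500, 800, 1),
                                     reflectance = 0.2))
  expect_error(resample_bsplines(short), "extrapolation")
  few <- as_raw_spectra(data.frame(plot_id = "F",
                                   wavelength = c(450, 600, 850),
                                   reflectance = 0.2))
  expect_error(resample_bsplines(few), "too few")
})

test_that("spectra IO round-trips in both long and wide layout", {
  raw <- filter_window(toy_raw_spectra(n_plots = 2, step = 1), 450, 850)
  long_path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(plot_id = raw$plot_id, wavelength_nm = raw$wavelength,
                   reflectance = raw$reflectance)
  write.csv(df, long_path, row.names = FALSE)
  back <- read_spectra(long_path)
  expect_equal(back$reflectance, raw$reflectance)

  rs <- resample_bsplines(raw)
  wide_path <- withr::local_tempfile(fileext = ".csv")
  write_resampled_spectra(rs, wide_path)
  back2 <- read_spectra(wide_path)
  expect_equal(sort(unique(back2$wavelength)), rs$band_centers)
  expect_equal(back2$reflectance[back2$plot_id == rs$plot_id[1]],
               unname(rs$X[1, ]), tolerance = 1e-12)
})

test_that("dataset assembly aligns rows with the spectra order", {
  set.seed(9)
  X <- matrix(runif(10 * 101), 10, 101)
  rs <- toy_resampled(X)
  # phenotype shuffled relative to spectra
  ord <- sample(10)
  ph <- as_phenotype(data.frame(
    plot_id = rs$plot_id[ord], year = 2010, genotype = paste0("G", ord),
    p_level = 0, rep = 1, grain_p = exp(ord / 10)))
  ds <- assemble_dataset(rs, ph)
  expect_equal(ds$n, 10); expect_equal(ds$p, 101)
  # explicit join oracle
  expect_equal(ds$y, ph$y[match(rs$plot_id, ph$plot_id)])
  expect_identical(ds$X, rs$X)

  ph_bad <- ph; ph_bad$plot_id <- paste0("Z", seq_len(10))
  expect_error(assemble_dataset(rs, ph_bad), "one-to-one")
})

test_that("phenotype construction validates grain_p and adds the log response", {
  df <- data.frame(plot_id = "a", year = 2010, genotype = "g", p_level = 0,
                   rep = 1, grain_p = 2.5)
  expect_equal(as_phenotype(df)$y, log(2.5))
  df$grain_p <- -1
  expect_error(as_phenotype(df), "positive")
})
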