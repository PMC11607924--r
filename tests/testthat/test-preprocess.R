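sim_m <- function(seed = 1, noise = 0.002, ...) {
  t1 <- load_table1_fixture()
  simulate_dataset(dplyr::filter(t1, set == "M"),
                   cfg = distortion_config(noise_sd = noise, seed = seed, ...))
}

test_that("band selection reproduces the analyte matrix dimensions", {
  sp <- sim_m()$spectra
  expect_equal(ncol(select_bands(sp, analyte_bands("GLM"))$absorbance), 190)
  expect_equal(ncol(select_bands(sp, analyte_bands("ALG"))$absorbance), 111)
  expect_equal(ncol(select_bands(sp, analyte_bands("PIO"))$absorbance), 111)
  expect_equal(ncol(select_bands(sp, band_selection(c(200, 400)))$absorbance), 401)

  # point counts follow (stop - start)/0.5 + 1 summed over bands
  bands <- list(c(210, 220.5), c(250, 251), c(399, 400))
  expected <- sum(vapply(bands, function(b) (b[2] - b[1]) / 0.5 + 1, 0))
  expect_equal(ncol(select_bands(sp, band_selection(bands))$absorbance), expected)

  expect_error(select_bands(sp, band_selection(c(230.25, 240))), "off-grid")
  expect_error(select_bands(sp, band_selection(c(150, 250))), "outside")
  expect_error(band_selection(c(240, 230)), "start")
  expect_error(band_selection(c(200, 250), c(240, 300)), "overlap")
})

test_that("mean centering and autoscaling fit on calibration and replay on new spectra", {
  sp <- sim_m()$spectra
  mc <- fit_centering(sp, "MC")
  expect_lt(max(abs(colMeans(mc$transformed$absorbance))), 1e-12)
  as_ <- fit_centering(sp, "AS")
  expect_equal(unname(apply(as_$transformed$absorbance, 2, sd)),
               rep(1, 401), tolerance = 1e-12)

  # a new spectrum equal to the calibration mean maps to the zero row
  mean_sp <- spectra_set(sp$wavelengths, matrix(colMeans(sp$absorbance), 1), "mean")
  expect_lt(max(abs(preprocess_apply(mc$state, mean_sp)$absorbance)), 1e-12)

  # fit/apply consistency: applying the state to the training set reproduces
  # the fitted transform
  expect_equal(preprocess_apply(as_$state, sp)$absorbance,
               as_$transformed$absorbance, tolerance = 1e-12)

  flat <- sp
  flat$absorbance[, 5] <- 1
  expect_error(fit_centering(flat, "AS"), "202")  # names the offending wavelength
})

test_that("SNV standardizes rows and is idempotent", {
  sp <- spectra_set(c(1, 2, 3), matrix(c(1, 2, 3, 5, 5, 8), 2, byrow = TRUE))
  out <- snv(sp)
  expect_equal(out$absorbance[1, ], c(-1, 0, 1))
  big <- sim_m()$spectra
  s1 <- snv(big)
  expect_lt(max(abs(rowMeans(s1$absorbance))), 1e-12)
  expect_equal(unname(apply(s1$absorbance, 1, sd)), rep(1, 25), tolerance = 1e-12)
  expect_equal(snv(s1)$absorbance, s1$absorbance, tolerance = 1e-12)
  const <- spectra_set(c(1, 2), matrix(1, 1, 2))
  expect_error(snv(const), "constant")
})

test_that("MSC removes multiplicative/additive scatter against the mean reference", {
  clean <- sim_m(noise = 0)$spectra
  fit <- msc_fit(clean)
  ref <- colMeans(clean$absorbance)

  # x = 2 ref + 1 corrects exactly back to the reference
  scaled <- spectra_set(clean$wavelengths, matrix(2 * ref + 1, 1), "s")
  expect_equal(drop(preprocess_apply(fit$state, scaled)$absorbance), ref,
               tolerance = 1e-10, ignore_attr = TRUE)
  # x = ref is unchanged
  same <- spectra_set(clean$wavelengths, matrix(ref, 1), "r")
  expect_equal(drop(preprocess_apply(fit$state, same)$absorbance), ref,
               tolerance = 1e-12, ignore_attr = TRUE)

  # random per-sample multiplicative/additive scatter on a common underlying
  # spectrum is inverted exactly: every corrected row returns to the shared
  # consensus spectrum (MSC's exactness domain is spectra affine in the
  # reference)
  set.seed(99)
  n <- 15
  slopes <- rnorm(n, 1, 0.1); offs <- rnorm(n, 0, 0.05)
  scat <- spectra_set(clean$wavelengths, outer(slopes, ref) + offs)
  fit2 <- msc_fit(scat)
  consensus <- colMeans(scat$absorbance)
  for (i in seq_len(n)) {
    expect_equal(fit2$transformed$absorbance[i, ], consensus,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("OSC removes y-orthogonal variation and replays on new spectra", {
  out <- sim_m(noise = 0.002, scatter_slope_sd = 0.05, scatter_offset_sd = 0.02)
  sp <- select_bands(out$spectra, analyte_bands("PIO"))
  y <- out$concentrations$PIO
  mc <- fit_centering(sp, "MC")
  osc <- osc_fit(mc$transformed, y, n_components = 2)

  # removed scores are orthogonal to y
  Xc <- mc$transformed$absorbance
  X_def <- osc$transformed$absorbance
  removed <- Xc - X_def
  sv <- svd(removed)
  for (k in 1:2) expect_lt(abs(cor(sv$u[, k], y)), 1e-8)

  # applying the fitted state to the calibration matrix reproduces the
  # deflated training matrix
  replay <- preprocess_apply(osc$state, mc$transformed)
  expect_lt(max(abs(replay$absorbance - X_def)), 1e-10)

  # identity and degenerate cases
  id <- osc_fit(mc$transformed, y, n_components = 0)
  expect_equal(id$transformed$absorbance, mc$transformed$absorbance)
  zero <- spectra_set(sp$wavelengths, matrix(0, 3, ncol(sp$absorbance)))
  expect_equal(preprocess_apply(osc$state, zero)$absorbance, zero$absorbance)

  expect_error(osc_fit(sp, y), "centred")
  short <- spectra_set(sp$wavelengths[1:10], Xc[, 1:10])
  expect_error(preprocess_apply(osc$state, short), "axis")
})

test_that("OSC on pure-signal data removes almost no variance", {
  # X = centred(y) s': every direction of X carries y information
  set.seed(4)
  y <- runif(20, 20, 30)
  s <- abs(rnorm(40))
  X <- outer(y - mean(y), s)
  sp <- spectra_set(seq(200, by = 0.5, length.out = 40), X)
  osc <- osc_fit(sp, y)
  removed_var <- sum((X - osc$transformed$absorbance)^2) / sum(X^2)
  expect_lt(removed_var, 0.01)
})

test_that("preprocessor states survive the JSON round trip", {
  out <- sim_m()
  sp <- select_bands(out$spectra, analyte_bands("ALG"))
  y <- out$concentrations$ALG
  mc <- fit_centering(sp, "MC")
  osc <- osc_fit(mc$transformed, y)
  for (state in list(mc$state, fit_centering(sp, "AS")$state,
                     msc_fit(sp)$state, osc$state)) {
    f <- withr::local_tempfile(fileext = ".json")
    write_preprocessor_json(state, f)
    back <- read_preprocessor_json(f)
    probe <- if (state$method == "OSC") mc$transformed else sp
    expect_equal(preprocess_apply(back, probe)$absorbance,
                 preprocess_apply(state, probe)$absorbance, tolerance = 1e-12)
  }
})

test_that("OSC improves PLS cross-validation under y-orthogonal scatter", {
  wins <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    out <- sim_m(seed = s, scatter_slope_sd = 0.05, scatter_offset_sd = 0.02,
                 baseline_drift_sd = 0.02)
    sp <- select_bands(out$spectra, analyte_bands("PIO"))
    y <- out$concentrations$PIO
    mc <- fit_centering(sp, "MC")$transformed
    plain <- min(loo_rmsecv(mc$absorbance, y, 6)$rmsecv)
    filtered <- min(loo_rmsecv(osc_fit(mc, y)$transformed$absorbance, y, 6)$rmsecv)
    if (filtered < plain) wins <- wins + 1L
  }
  # one-sided sign test at the 5% level
  expect_lt(binom.test(wins, n_seeds, 0.5, alternative = "greater")$p.value, 0.05)
})
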