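test_that("SIMPLS recovers exact low-rank structure", {
  # rank-1 X: one latent variable reproduces y exactly
  set.seed(11)
  t_true <- rnorm(15)
  X <- outer(t_true, rnorm(6))
  y <- 2 * t_true + 5
  fit <- simpls_fit(X, y, max_lv = 1, run_cv = FALSE)
  expect_equal(pls_predict(fit, X, 1), y, tolerance = 1e-8)

  # univariate X: the 1-LV regression vector equals the OLS slope
  x1 <- matrix(rnorm(20), 20, 1)
  y1 <- 3 * x1[, 1] + rnorm(20, sd = 0.1)
  fit1 <- simpls_fit(x1, y1, max_lv = 1, run_cv = FALSE)
  ols <- coef(lm(y1 ~ x1[, 1]))
  expect_equal(fit1$coefficients[1, 1], unname(ols[2]), tolerance = 1e-10)

  # full-rank noiseless linear data is reproduced at max LV
  d <- random_calibration(21)
  fitf <- simpls_fit(d$X, drop(d$X %*% rnorm(8)), max_lv = 8, run_cv = FALSE)
  yf <- drop(d$X %*% rnorm(8))
  fitf2 <- simpls_fit(d$X, yf, max_lv = 8, run_cv = FALSE)
  expect_equal(pls_predict(fitf2, d$X, 8), yf, tolerance = 1e-8)

  # n_lv = 0 predicts the training mean
  expect_equal(pls_predict(fit1, x1, 0), rep(mean(y1), 20))

  expect_error(simpls_fit(d$X, rep(1, 12), 3), "variance")
  expect_error(simpls_fit(d$X, d$y, 50), "exceeds")
})

test_that("SIMPLS predictions match the NIPALS PLS1 oracle on random matrices", {
  for (seed in 1:25) {
    d <- random_calibration(seed, n = 10 + seed %% 5, p = 5 + seed %% 4)
    max_lv <- min(nrow(d$X) - 1, ncol(d$X), 6)
    fit <- simpls_fit(d$X, d$y, max_lv = max_lv, run_cv = FALSE)
    oracle <- nipals_pls1(d$X, d$y, max_lv)
    set.seed(seed + 1000)
    Xnew <- matrix(rnorm(3 * ncol(d$X)), 3)
    for (h in seq_len(max_lv)) {
      expect_equal(pls_predict(fit, Xnew, h), oracle$predict(Xnew, h),
                   tolerance = 1e-8)
    }
  }
})

test_that("training residuals are non-increasing in the number of LVs", {
  for (seed in c(3, 17)) {
    d <- random_calibration(seed, n = 14, p = 9)
    fit <- simpls_fit(d$X, d$y, max_lv = 8, run_cv = FALSE)
    rss <- vapply(1:8, function(h) sum((pls_predict(fit, d$X, h) - d$y)^2), 0)
    expect_true(all(diff(rss) <= 1e-10))
  }
})

test_that("leave-one-out RMSECV matches an independent refit loop", {
  d <- random_calibration(7, n = 10, p = 6)
  cv <- loo_rmsecv(d$X, d$y, 4)
  expect_length(cv$press, 4)
  expect_equal(cv$n_heldout, 10)

  # independent computation through the public fitting interface
  press2 <- numeric(4)
  for (i in 1:10) {
    fit <- simpls_fit(d$X[-i, ], d$y[-i], max_lv = 4, run_cv = FALSE)
    for (h in 1:4) {
      press2[h] <- press2[h] +
        (pls_predict(fit, d$X[i, , drop = FALSE], h) - d$y[i])^2
    }
  }
  expect_equal(cv$press, press2, tolerance = 1e-12)
  expect_equal(cv$rmsecv, sqrt(press2 / 10), tolerance = 1e-12)

  # perfect rank-3 data: three LVs drive RMSECV to numerical zero
  set.seed(2)
  scoresT <- matrix(rnorm(45), 15, 3)
  X3 <- scoresT %*% matrix(rnorm(24), 3, 8)
  y3 <- drop(scoresT %*% c(1, -2, 0.5)) + 10
  cv3 <- loo_rmsecv(X3, y3, 5)
  expect_lt(cv3$rmsecv[3], 1e-6)
})

test_that("Haaland-Thomas picks the most parsimonious near-minimal model", {
  # steep strictly decreasing curve: the minimum itself is chosen
  steep <- c(100, 10, 1, 0.1)
  expect_equal(select_lv_haaland(steep, n = 25)$n_lv, 4)
  # flat beyond rank 2: rank 2 is chosen over later equally good ranks
  flat <- c(100, 1, 1, 1)
  expect_equal(select_lv_haaland(flat, n = 25)$n_lv, 2)
  expect_error(select_lv_haaland(c(1, NA), 10), "finite")

  # three-component mixtures with mild noise settle at 3 LVs (modal choice)
  t1 <- load_table1_fixture()
  m <- dplyr::filter(t1, set == "M")
  choices <- vapply(1:20, function(s) {
    sim <- simulate_dataset(m, cfg = distortion_config(noise_sd = 0.002, seed = s))
    sp <- select_bands(sim$spectra, analyte_bands("ALG"))
    mc <- fit_centering(sp, "MC")$transformed
    simpls_fit(mc, sim$concentrations$ALG, max_lv = 8)$n_lv
  }, 0L)
  modal <- as.integer(names(which.max(table(choices))))
  expect_equal(modal, 3L)
})

test_that("score compression yields orthogonal projectable scores", {
  out <- simulate_dataset(dplyr::filter(load_table1_fixture(), set == "M"),
                          cfg = distortion_config(seed = 3))
  sp <- select_bands(out$spectra, analyte_bands("ALG"))
  y <- out$concentrations$ALG

  pca <- compress(sp, k = 4, method = "PCA")
  expect_equal(dim(pca$scores), c(25, 4))
  gram <- crossprod(pca$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)

  pls <- compress(sp, y, k = 3, method = "PLS")
  expect_equal(dim(pls$scores), c(25, 3))

  # projecting the calibration spectra reproduces the stored scores
  expect_lt(max(abs(compress_project(pca, sp) - pca$scores)), 1e-10)
  expect_lt(max(abs(compress_project(pls, sp) - pls$scores)), 1e-10)

  expect_error(compress(sp, y, k = 30, method = "PLS"), "rank")
  expect_error(compress(sp, k = 26, method = "PCA"), "rank")
  expect_error(compress(sp, k = 2, method = "PLS"), "requires y")
})

test_that("PLS model JSON round trip preserves predictions", {
  d <- random_calibration(5)
  fit <- simpls_fit(d$X, d$y, max_lv = 5, run_cv = FALSE)
  f <- withr::local_tempfile(fileext = ".json")
  write_pls_json(fit, f)
  back <- read_pls_json(f)
  set.seed(1); Xnew <- matrix(rnorm(16), 2)
  expect_equal(pls_predict(back, Xnew, 5), pls_predict(fit, Xnew, 5),
               tolerance = 1e-12)
})
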