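test_that("single stump on two points reproduces the closed form", {
  X <- matrix(c(0, 1))
  y <- c(0, 1)
  m <- gbt_fit(X, y, gbt_config(eta = 1, max_depth = 1, num_round = 1, lambda = 0))
  tree <- m$trees[[1]]
  expect_false(tree$leaf)
  expect_equal(tree$threshold, 0.5)
  expect_equal(tree$left$value, -0.5)   # -G/(H+0) with g = 0.5 at x = 0
  expect_equal(tree$right$value, 0.5)
  expect_equal(gbt_predict(m, X), c(0, 1))
})

test_that("extreme regularization collapses predictions to the mean", {
  d <- random_calibration(2, n = 10, p = 2)
  m <- gbt_fit(d$X, d$y, gbt_config(eta = 1, max_depth = 3, num_round = 5,
                                    lambda = 1e12))
  expect_equal(gbt_predict(m, d$X), rep(mean(d$y), 10), tolerance = 1e-6)

  # a split penalty no tree can pay yields pure base-score predictions
  m0 <- gbt_fit(d$X, d$y, gbt_config(eta = 1, max_depth = 3, num_round = 3,
                                     gamma = 1e12))
  expect_equal(gbt_predict(m0, d$X), rep(mean(d$y), 10))
})

test_that("split search agrees with exhaustive enumeration", {
  set.seed(31)
  for (rep in 1:10) {
    X <- matrix(round(rnorm(18), 2), 6, 3)
    g <- rnorm(6)
    oracle <- brute_force_split(X, g, lambda = 1, gamma = 0, min_child = 1)
    got <- mixcal:::find_best_split(X, g, seq_len(6), 1, 0, 1)
    expect_equal(got$gain, oracle$gain, tolerance = 1e-12)
    if (oracle$gain > 0) {
      expect_equal(got$feature, oracle$feature)
      expect_equal(got$threshold, oracle$threshold)
      # leaf weights of the resulting children match -G/(H+lambda)
      left <- X[, got$feature] < got$threshold
      expect_equal(-sum(g[left]) / (sum(left) + 1), oracle$w_left)
      expect_equal(-sum(g[!left]) / (sum(!left) + 1), oracle$w_right)
    }
  }
})

test_that("training loss is non-increasing and predictions are row-independent", {
  for (seed in c(1, 8)) {
    d <- random_calibration(seed, n = 15, p = 4)
    m <- gbt_fit(d$X, d$y, gbt_config(eta = 0.3, max_depth = 3, num_round = 40,
                                      seed = seed))
    expect_true(all(diff(m$loss_trace) <= 1e-12))
    # the stored trace endpoint is reproduced by predicting the training set
    expect_equal(mean((gbt_predict(m, d$X) - d$y)^2),
                 m$loss_trace[length(m$loss_trace)], tolerance = 1e-12)
    perm <- sample(nrow(d$X))
    expect_equal(gbt_predict(m, d$X[perm, ]), gbt_predict(m, d$X)[perm])
  }
})

test_that("predictions match xgboost configured identically", {
  library(xgboost)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    X <- matrix(rnorm(n * 3), n, 3)
    y <- drop(X %*% c(2, -1, 0.5)) + 0.3 * X[, 1]^2 + rnorm(n, sd = 0.2)
    cfg <- gbt_config(eta = 0.3, max_depth = 3, num_round = 15, lambda = 1,
                      gamma = 0, min_child_weight = 1)
    mine <- gbt_fit(X, y, cfg)
    ref <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = cfg$eta,
                    max_depth = cfg$max_depth, lambda = cfg$lambda,
                    gamma = cfg$gamma, min_child_weight = cfg$min_child_weight,
                    base_score = mean(y), tree_method = "exact", nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = cfg$num_round,
      verbose = 0)
    expect_equal(gbt_predict(mine, X),
                 as.numeric(predict(ref, xgboost::xgb.DMatrix(X))),
                 tolerance = 1e-6)
  }
})

test_that("cross-validated parameter selection is deterministic and guards overfit", {
  d <- random_calibration(12, n = 20, p = 3)
  grid1 <- data.frame(eta = 0.3, max_depth = 2, num_round = 10)
  sel1 <- gbt_cv_select(d$X, d$y, grid1, folds = 4, seed = 9)
  expect_equal(nrow(sel1$cv_table), 1)
  expect_equal(sel1$best$max_depth, 2L)

  grid <- expand.grid(eta = c(0.1, 0.5), max_depth = c(1, 4),
                      num_round = c(5, 50))
  sel <- gbt_cv_select(d$X, d$y, grid, folds = 4, seed = 9)
  expect_equal(nrow(sel$cv_table), nrow(grid))
  sel_again <- gbt_cv_select(d$X, d$y, grid, folds = 4, seed = 9)
  expect_identical(sel$cv_table$mean_rmse, sel_again$cv_table$mean_rmse)

  expect_error(gbt_cv_select(d$X, d$y, grid, folds = 30), "folds")

  # pure-noise response: the small configuration wins more often than not
  small_grid <- data.frame(eta = 0.3, max_depth = c(1, 4), num_round = c(5, 80))
  small_wins <- 0L
  for (s in 1:20) {
    set.seed(s + 400)
    Xn <- matrix(rnorm(60), 20, 3)
    yn <- rnorm(20)
    pick <- gbt_cv_select(Xn, yn, small_grid, folds = 4, seed = s)$best
    if (pick$num_round == 5L) small_wins <- small_wins + 1L
  }
  expect_gt(small_wins, 10L)
})

test_that("GBT model JSON round trip preserves predictions", {
  d <- random_calibration(6, n = 12, p = 3)
  m <- gbt_fit(d$X, d$y, gbt_config(eta = 0.2, max_depth = 3, num_round = 12))
  f <- withr::local_tempfile(fileext = ".json")
  write_gbt_json(m, f)
  back <- read_gbt_json(f)
  set.seed(3); Xn <- matrix(rnorm(9), 3)
  expect_equal(gbt_predict(back, Xn), gbt_predict(m, Xn), tolerance = 1e-12)
})
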