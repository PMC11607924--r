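# nu-SVR and single-hidden-layer ANN adapters. Both expose the same
# fit/predict surface as the PLS and boosted-tree models so the evaluation
# pipeline is model-agnostic. The SVR quadratic program is delegated to
# e1071 (libsvm); the ANN trainer is a compact full-batch backpropagation
# loop so that the learning-rate and monitor-set early-stopping contract is
# explicit and deterministic.

#' nu-SVR configuration
#'
#' RBF kernel throughout. Shipped presets: ALG and PIO use `C = 100`,
#' `gamma = 0.1`; GLM uses `C = 31.623`, `gamma = 3.162`. The nu default is
#' 0.5 (a conventional midpoint; no preset value is asserted for it).
#'
#' @param cost Regularization constant C > 0.
#' @param nu Fraction bound on support vectors, in (0, 1].
#' @param gamma RBF kernel width parameter > 0 (applied to internally
#'   standardized features).
#' @return Object of class `svr_config`.
#' @export
svr_config <- function(cost = 100, nu = 0.5, gamma = 0.1) {
  assert_scalar_number(cost, "cost", min = 0, strict_min = TRUE)
  assert_scalar_number(gamma, "gamma", min = 0, strict_min = TRUE)
  if (nu <= 0 || nu > 1) stop_mixcal("nu must be in (0, 1]")
  structure(list(cost = cost, nu = nu, gamma = gamma), class = "svr_config")
}

#' Fit a nu-SVR regressor with RBF kernel
#'
#' Features and response are standardized internally (stored with the model);
#' `gamma` therefore acts on unit-variance features. Given identical data and
#' configuration the fitted predictions are reproducible to well below 1e-6.
#'
#' @param features Numeric matrix or `score_matrix`.
#' @param y Response vector; must not be constant.
#' @param cfg An [svr_config()].
#' @return Object of class `svr_model`.
#' @export
svr_fit <- function(features, y, cfg = svr_config()) {
  X <- if (inherits(features, "score_matrix")) features$scores else as.matrix(features)
  y <- as.numeric(y)
  stopifnot(inherits(cfg, "svr_config"))
  if (length(y) != nrow(X)) stop_mixcal("length(y) must equal nrow(features)")
  if (stats::sd(y) == 0) stop_mixcal("y is constant; nu-SVR fit is degenerate")
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale < 1e-12] <- 1
  y_center <- mean(y); y_scale <- stats::sd(y)
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  fit <- e1071::svm(Xs, (y - y_center) / y_scale, type = "nu-regression",
                    kernel = "radial", cost = cfg$cost, nu = cfg$nu,
                    gamma = cfg$gamma, scale = FALSE)
  structure(list(fit = fit, cfg = cfg, x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 n_features = ncol(X)),
            class = "svr_model")
}

#' Predict from a fitted nu-SVR model
#'
#' @param model An `svr_model`.
#' @param features New feature matrix.
#' @return Numeric prediction vector on the original response scale.
#' @export
svr_predict <- function(model, features) {
  stopifnot(inherits(model, "svr_model"))
  X <- if (inherits(features, "score_matrix")) features$scores else as.matrix(features)
  if (ncol(X) != model$n_features) stop_mixcal("feature count mismatch")
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  drop(stats::predict(model$fit, Xs)) * model$y_scale + model$y_center
}

#' ANN configuration
#'
#' Single hidden layer, feed-forward, trained by full-batch backpropagation
#' (gradient descent on squared error). The default learning rate is 0.125.
#' Training stops at `max_epochs`, or earlier when the monitor-set RMSEP has
#' risen above its best value for `patience` consecutive epochs while the
#' training error keeps falling -- the classical early-stopping signal for
#' incipient overfitting.
#'
#' @param hidden Hidden-layer size (>= 1).
#' @param learning_rate Gradient-descent step, default 0.125.
#' @param max_epochs Maximum training epochs.
#' @param patience Consecutive monitor deteriorations tolerated before
#'   stopping; 0 stops at the first rise.
#' @param activation `"tanh"` or `"sigmoid"` hidden transfer function. Both
#'   are offered; tanh is the default.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `ann_config`.
#' @export
ann_config <- function(hidden = 5, learning_rate = 0.125, max_epochs = 2000,
                       patience = 20, activation = c("tanh", "sigmoid"),
                       seed = 1L) {
  if (hidden < 1 || hidden != round(hidden)) stop_mixcal("hidden size must be >= 1")
  assert_scalar_number(learning_rate, "learning_rate", min = 0, strict_min = TRUE)
  activation <- match.arg(activation)
  structure(list(hidden = as.integer(hidden), learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), activation = activation,
                 seed = as.integer(seed)),
            class = "ann_config")
}

act_fun <- function(z, activation) {
  if (activation == "tanh") tanh(z) else 1 / (1 + exp(-z))
}
act_grad <- function(a, activation) {
  if (activation == "tanh") 1 - a^2 else a * (1 - a)
}

#' Fit a single-hidden-layer backpropagation network
#'
#' Inputs are typically compressed scores from [compress()]. Features and the
#' response are standardized internally; the output unit is linear. Weights
#' are initialized from a seeded uniform draw, so a fixed seed yields an
#' identical loss trace. When `monitor_features`/`monitor_y` are supplied
#' (they must be disjoint from the training rows), the monitor RMSEP is
#' tracked per epoch and training stops early once it has exceeded its best
#' value for more than `patience` consecutive epochs; the weights from the
#' best-monitor epoch are kept.
#'
#' @param features Training feature matrix or `score_matrix`.
#' @param y Training response.
#' @param cfg An [ann_config()].
#' @param monitor_features,monitor_y Optional held-out monitor set.
#' @return Object of class `ann_model` with `train_trace` and, if monitored,
#'   `monitor_trace` and `stopped_epoch`.
#' @export
ann_fit <- function(features, y, cfg = ann_config(), monitor_features = NULL,
                    monitor_y = NULL) {
  X <- if (inherits(features, "score_matrix")) features$scores else as.matrix(features)
  y <- as.numeric(y)
  stopifnot(inherits(cfg, "ann_config"))
  if (length(y) != nrow(X)) stop_mixcal("length(y) must equal nrow(features)")
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd); x_scale[x_scale < 1e-12] <- 1
  y_center <- mean(y); y_scale <- stats::sd(y)
  if (y_scale == 0) y_scale <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale
  n <- nrow(Xs); p <- ncol(Xs); h <- cfg$hidden

  Xm <- NULL; ym <- NULL
  if (!is.null(monitor_features)) {
    Xm <- if (inherits(monitor_features, "score_matrix")) {
      monitor_features$scores
    } else as.matrix(monitor_features)
    Xm <- sweep(sweep(Xm, 2, x_center), 2, x_scale, "/")
    ym <- as.numeric(monitor_y)
  }

  W1 <- with_substream(cfg$seed, 1L,
                       matrix(stats::runif((p + 1) * h, -0.5, 0.5), p + 1, h))
  W2 <- with_substream(cfg$seed, 2L, stats::runif(h + 1, -0.5, 0.5))

  forward <- function(Xin, W1, W2) {
    A <- act_fun(cbind(1, Xin) %*% W1, cfg$activation)
    list(hidden = A, out = drop(cbind(1, A) %*% W2))
  }

  train_trace <- numeric(0); monitor_trace <- numeric(0)
  best_monitor <- Inf; best_W1 <- W1; best_W2 <- W2; bad <- 0L
  stopped_epoch <- cfg$max_epochs
  for (epoch in seq_len(cfg$max_epochs)) {
    fw <- forward(Xs, W1, W2)
    err <- fw$out - ys                       # d(loss)/d(out), loss = mean(err^2)/2
    dW2 <- drop(crossprod(cbind(1, fw$hidden), err)) / n
    dHidden <- (err %o% W2[-1]) * act_grad(fw$hidden, cfg$activation)
    dW1 <- crossprod(cbind(1, Xs), dHidden) / n
    W2 <- W2 - cfg$learning_rate * dW2
    W1 <- W1 - cfg$learning_rate * dW1
    fw2 <- forward(Xs, W1, W2)
    train_trace[epoch] <- sqrt(mean((fw2$out - ys)^2)) * y_scale
    if (!is.null(Xm)) {
      pm <- forward(Xm, W1, W2)$out * y_scale + y_center
      monitor_trace[epoch] <- sqrt(mean((pm - ym)^2))
      if (monitor_trace[epoch] < best_monitor - 1e-12) {
        best_monitor <- monitor_trace[epoch]
        best_W1 <- W1; best_W2 <- W2; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad > cfg$patience) { stopped_epoch <- epoch; break }
      }
    }
  }
  if (is.null(Xm)) { best_W1 <- W1; best_W2 <- W2 }
  structure(list(W1 = best_W1, W2 = best_W2, cfg = cfg,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 n_features = p, train_trace = train_trace,
                 monitor_trace = if (length(monitor_trace)) monitor_trace,
                 stopped_epoch = stopped_epoch),
            class = "ann_model")
}

#' Predict from a fitted network
#'
#' @param model An `ann_model`.
#' @param features New feature matrix.
#' @return Numeric prediction vector on the original response scale.
#' @export
ann_predict <- function(model, features) {
  stopifnot(inherits(model, "ann_model"))
  X <- if (inherits(features, "score_matrix")) features$scores else as.matrix(features)
  if (ncol(X) != model$n_features) stop_mixcal("feature count mismatch")
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  A <- act_fun(cbind(1, Xs) %*% model$W1, model$cfg$activation)
  drop(cbind(1, A) %*% model$W2) * model$y_scale + model$y_center
}

#' Sweep hidden-layer sizes by monitor RMSEP
#'
#' The trial-and-error architecture search: fits one network per candidate
#' hidden size and reports training and monitor RMSEP, so the smallest
#' adequate architecture can be chosen.
#'
#' @param features,y Training data.
#' @param monitor_features,monitor_y Monitor set (disjoint from training).
#' @param hidden_sizes Candidate hidden-layer sizes.
#' @param cfg Base [ann_config()]; `hidden` is overridden per candidate.
#' @return Tibble: `hidden`, `train_rmsep`, `monitor_rmsep`, `stopped_epoch`.
#' @export
ann_hidden_sweep <- function(features, y, monitor_features, monitor_y,
                             hidden_sizes = 1:8, cfg = ann_config()) {
  purrr::map_dfr(hidden_sizes, function(h) {
    cfg_h <- cfg; cfg_h$hidden <- as.integer(h)
    m <- ann_fit(features, y, cfg_h, monitor_features, monitor_y)
    tibble::tibble(
      hidden = h,
      train_rmsep = m$train_trace[length(m$train_trace)],
      monitor_rmsep = min(m$monitor_trace),
      stopped_epoch = m$stopped_epoch)
  })
}
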