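# Regularized gradient-boosted regression trees with exact greedy splits
# (squared-error objective, unit hessians). Written for the small-n regime of
# calibration designs, where exact enumeration of every candidate split is
# cheap and histogram approximations buy nothing.

#' Gradient-boosted tree configuration
#'
#' @param eta Learning rate in (0, 1].
#' @param max_depth Maximum tree depth (>= 1; 1 gives stumps).
#' @param num_round Number of boosting rounds (>= 1).
#' @param lambda L2 regularizer on leaf weights (>= 0), default 1.
#' @param gamma Minimum gain required to keep a split (>= 0), default 0.
#' @param min_child_weight Minimum hessian sum per child; with unit hessians
#'   this is the minimum sample count per leaf. Default 1.
#' @param cv_folds Folds used by [gbt_cv_select()], default 5.
#' @param seed Integer seed for deterministic fold assignment.
#' @return Object of class `gbt_config`.
#' @export
gbt_config <- function(eta = 0.3, max_depth = 4, num_round = 100, lambda = 1,
                       gamma = 0, min_child_weight = 1, cv_folds = 5, seed = 1L) {
  assert_scalar_number(eta, "eta", min = 0, strict_min = TRUE)
  if (eta > 1) stop_mixcal("eta must be in (0, 1]")
  if (max_depth < 1 || max_depth != round(max_depth)) {
    stop_mixcal("max_depth must be an integer >= 1")
  }
  if (num_round < 1 || num_round != round(num_round)) {
    stop_mixcal("num_round must be an integer >= 1")
  }
  assert_scalar_number(lambda, "lambda", min = 0)
  assert_scalar_number(gamma, "gamma", min = 0)
  assert_scalar_number(min_child_weight, "min_child_weight", min = 0)
  structure(list(eta = eta, max_depth = as.integer(max_depth),
                 num_round = as.integer(num_round), lambda = lambda,
                 gamma = gamma, min_child_weight = min_child_weight,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "gbt_config")
}

# Exact greedy best split for one node. Gain:
#   1/2 [ GL^2/(HL+l) + GR^2/(HR+l) - (GL+GR)^2/(HL+HR+l) ] - gamma
# Candidate thresholds are midpoints between consecutive sorted unique
# feature values; strictly-less-than goes left. Ties broken by lowest feature
# index, then lowest threshold (first candidate found wins, search is ordered).
find_best_split <- function(X, g, idx, lambda, gamma, min_child_weight) {
  Gtot <- sum(g[idx]); Htot <- length(idx)
  parent <- Gtot^2 / (Htot + lambda)
  best <- list(gain = 0)
  for (j in seq_len(ncol(X))) {
    x <- X[idx, j]
    o <- order(x)
    xs <- x[o]; gs <- g[idx][o]
    uniq <- which(diff(xs) > 0)          # split after position i
    if (length(uniq) == 0L) next
    cg <- cumsum(gs)
    for (i in uniq) {
      HL <- i; HR <- Htot - i
      if (HL < min_child_weight || HR < min_child_weight) next
      GL <- cg[i]; GR <- Gtot - GL
      gain <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - parent) - gamma
      if (gain > best$gain + 1e-12) {
        best <- list(gain = gain, feature = j,
                     threshold = (xs[i] + xs[i + 1]) / 2)
      }
    }
  }
  best
}

build_tree <- function(X, g, idx, depth, cfg) {
  make_leaf <- function() {
    list(leaf = TRUE, value = -sum(g[idx]) / (length(idx) + cfg$lambda))
  }
  if (depth >= cfg$max_depth || length(idx) < 2L) return(make_leaf())
  sp <- find_best_split(X, g, idx, cfg$lambda, cfg$gamma, cfg$min_child_weight)
  if (sp$gain <= 0) return(make_leaf())
  left <- idx[X[idx, sp$feature] < sp$threshold]
  right <- setdiff(idx, left)
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       gain = sp$gain,
       left = build_tree(X, g, left, depth + 1L, cfg),
       right = build_tree(X, g, right, depth + 1L, cfg))
}

tree_predict_one <- function(node, x) {
  while (!node$leaf) {
    node <- if (x[node$feature] < node$threshold) node$left else node$right
  }
  node$value
}

tree_predict <- function(node, X) {
  apply(X, 1, function(x) tree_predict_one(node, x))
}

#' Fit a gradient-boosted regression tree ensemble
#'
#' Squared-error boosting with unit hessians: at each round the gradients are
#' `g_i = yhat_i - y_i`, a regression tree is grown by exact greedy search
#' over every feature and every midpoint between consecutive sorted unique
#' values (gain formula with L2 leaf penalty `lambda` and split penalty
#' `gamma`; a node is split only when the best gain is positive), leaf
#' weights are `-G/(H + lambda)`, and predictions advance by `eta` times the
#' tree output from `base_score = mean(y)`. The training squared-loss trace
#' is recorded and is non-increasing for `eta <= 1`.
#'
#' @param features Numeric matrix (or `score_matrix`) of predictors.
#' @param y Response vector.
#' @param cfg A [gbt_config()].
#' @return Object of class `gbt_model`: `base_score`, `trees`, `cfg`,
#'   `loss_trace` (training MSE per round).
#' @export
gbt_fit <- function(features, y, cfg = gbt_config()) {
  X <- if (inherits(features, "score_matrix")) features$scores else as.matrix(features)
  y <- as.numeric(y)
  if (nrow(X) == 0L) stop_mixcal("empty feature matrix")
  if (length(y) != nrow(X)) stop_mixcal("length(y) must equal nrow(features)")
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop_mixcal("features and y must be finite")
  }
  stopifnot(inherits(cfg, "gbt_config"))
  n <- nrow(X)
  base_score <- mean(y)
  pred <- rep(base_score, n)
  trees <- vector("list", cfg$num_round)
  loss_trace <- numeric(cfg$num_round)
  idx <- seq_len(n)
  for (r in seq_len(cfg$num_round)) {
    g <- pred - y
    tree <- build_tree(X, g, idx, 0L, cfg)
    pred <- pred + cfg$eta * tree_predict(tree, X)
    trees[[r]] <- tree
    loss_trace[r] <- mean((pred - y)^2)
  }
  structure(list(base_score = base_score, trees = trees, cfg = cfg,
                 n_features = ncol(X), loss_trace = loss_trace),
            class = "gbt_model")
}

#' @export
print.gbt_model <- function(x, ...) {
  cat(sprintf("<gbt_model: %d rounds, eta %.3g, max_depth %d, final MSE %.4g>\n",
              length(x$trees), x$cfg$eta, x$cfg$max_depth,
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Predict from a gradient-boosted tree ensemble
#'
#' Deterministic traversal: a feature value strictly less than the node
#' threshold goes left. `prediction = base_score + eta * sum(tree outputs)`.
#'
#' @param model A `gbt_model`.
#' @param features New feature matrix with the fitted column count.
#' @return Numeric prediction vector.
#' @export
gbt_predict <- function(model, features) {
  stopifnot(inherits(model, "gbt_model"))
  X <- if (inherits(features, "score_matrix")) features$scores else as.matrix(features)
  if (ncol(X) != model$n_features) stop_mixcal("feature count mismatch")
  pred <- rep(model$base_score, nrow(X))
  for (tree in model$trees) {
    pred <- pred + model$cfg$eta * tree_predict(tree, X)
  }
  pred
}

#' Select gradient-boosting hyperparameters by cross-validation
#'
#' Deterministic k-fold assignment derived from `seed`; for every grid point
#' the mean held-out RMSE over folds is computed and the lowest wins, ties
#' broken by smaller `num_round`, then smaller `max_depth`, then smaller
#' `eta`.
#'
#' @param features Feature matrix.
#' @param y Response vector.
#' @param grid Data frame with columns `eta`, `max_depth`, `num_round` (other
#'   [gbt_config()] fields optional).
#' @param folds Number of folds (>= 2, <= n).
#' @param seed Integer seed for the fold split.
#' @return List with `best` (a [gbt_config()]) and `cv_table` (tibble: grid +
#'   `mean_rmse`).
#' @export
gbt_cv_select <- function(features, y, grid, folds = 5, seed = 1L) {
  X <- if (inherits(features, "score_matrix")) features$scores else as.matrix(features)
  y <- as.numeric(y)
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0L) stop_mixcal("empty parameter grid")
  n <- nrow(X)
  if (folds < 2L) stop_mixcal("folds must be >= 2")
  if (folds > n) stop_mixcal("more folds than samples")
  fold_id <- with_substream(seed, 0L, sample(rep(seq_len(folds), length.out = n)))
  col_or <- function(nm, default) {
    if (nm %in% names(grid)) grid[[nm]] else rep(default, nrow(grid))
  }
  lam <- col_or("lambda", 1); gam <- col_or("gamma", 0)
  mcw <- col_or("min_child_weight", 1)
  mean_rmse <- vapply(seq_len(nrow(grid)), function(gi) {
    cfg <- gbt_config(
      eta = grid$eta[gi], max_depth = grid$max_depth[gi],
      num_round = grid$num_round[gi], lambda = lam[gi], gamma = gam[gi],
      min_child_weight = mcw[gi], cv_folds = folds, seed = seed)
    rmse <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      m <- gbt_fit(X[tr, , drop = FALSE], y[tr], cfg)
      sqrt(mean((gbt_predict(m, X[!tr, , drop = FALSE]) - y[!tr])^2))
    }, 0)
    mean(rmse)
  }, 0)
  cv_table <- dplyr::mutate(grid, mean_rmse = mean_rmse)
  ord <- order(cv_table$mean_rmse, cv_table$num_round, cv_table$max_depth,
               cv_table$eta)
  bi <- ord[1]
  best <- gbt_config(eta = grid$eta[bi], max_depth = grid$max_depth[bi],
                     num_round = grid$num_round[bi], lambda = lam[bi],
                     gamma = gam[bi], min_child_weight = mcw[bi],
                     cv_folds = folds, seed = seed)
  list(best = best, cv_table = cv_table)
}

#' Serialize / restore a gradient-boosted tree model as JSON
#'
#' @param model A `gbt_model`.
#' @param path File path.
#' @name gbt_io
#' @export
write_gbt_json <- function(model, path) {
  stopifnot(inherits(model, "gbt_model"))
  jsonlite::write_json(
    list(base_score = model$base_score, n_features = model$n_features,
         cfg = unclass(model$cfg), loss_trace = model$loss_trace,
         trees = model$trees),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gbt_io
#' @export
read_gbt_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) if (is.null(v)) NULL else as.numeric(v)
  fix_tree <- function(node) {
    if (isTRUE(node$leaf)) {
      list(leaf = TRUE, value = as.numeric(node$value))
    } else {
      list(leaf = FALSE, feature = as.integer(node$feature),
           threshold = as.numeric(node$threshold), gain = num(node$gain),
           left = fix_tree(node$left), right = fix_tree(node$right))
    }
  }
  cfg <- do.call(gbt_config, lapply(x$cfg, function(v) v))
  structure(list(base_score = as.numeric(x$base_score),
                 trees = lapply(x$trees, fix_tree), cfg = cfg,
                 n_features = as.integer(x$n_features),
                 loss_trace = as.numeric(unlist(x$loss_trace))),
            class = "gbt_model")
}
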