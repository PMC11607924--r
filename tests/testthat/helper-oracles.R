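# Independent oracles used across the suite. These deliberately share no code
# with the package implementation.

# Classical NIPALS PLS1: deflates X per component, regression vector
# B_h = W_h (P_h' W_h)^{-1} q_h. Prediction-equivalent to SIMPLS for a single
# response; used as the algorithm-equivalence oracle.
nipals_pls1 <- function(X, y, max_lv) {
  X <- as.matrix(X); y <- as.numeric(y)
  x_center <- colMeans(X); y_center <- mean(y)
  Xd <- sweep(X, 2, x_center)
  yc <- y - y_center
  p <- ncol(X)
  W <- P <- matrix(0, p, max_lv)
  q <- numeric(max_lv)
  for (a in seq_len(max_lv)) {
    w <- drop(crossprod(Xd, yc))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xd %*% w)
    pa <- drop(crossprod(Xd, t)) / sum(t^2)
    q[a] <- sum(yc * t) / sum(t^2)
    Xd <- Xd - tcrossprod(t, pa)
    W[, a] <- w; P[, a] <- pa
  }
  predict_at <- function(Xnew, h) {
    Wh <- W[, seq_len(h), drop = FALSE]
    Ph <- P[, seq_len(h), drop = FALSE]
    B <- Wh %*% solve(crossprod(Ph, Wh), q[seq_len(h)])
    drop(sweep(as.matrix(Xnew), 2, x_center) %*% B) + y_center
  }
  list(predict = predict_at)
}

# Exhaustive enumeration of every axis-aligned split of one node: for each
# feature and each midpoint between consecutive sorted unique values, compute
# the regularized gain and the two child leaf weights directly from the
# definitions. Returns the best (gain, feature, threshold, left/right weight).
brute_force_split <- function(X, g, lambda = 1, gamma = 0, min_child = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  Gt <- sum(g); Ht <- n
  best <- list(gain = 0, feature = NA, threshold = NA)
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2) next
    for (i in seq_len(length(u) - 1)) {
      thr <- (u[i] + u[i + 1]) / 2
      left <- X[, j] < thr
      HL <- sum(left); HR <- n - HL
      if (HL < min_child || HR < min_child) next
      GL <- sum(g[left]); GR <- Gt - GL
      gain <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) -
                       Gt^2 / (Ht + lambda)) - gamma
      if (gain > best$gain + 1e-12) {
        best <- list(gain = gain, feature = j, threshold = thr,
                     w_left = -GL / (HL + lambda), w_right = -GR / (HR + lambda))
      }
    }
  }
  best
}

# Small random spectra-like matrix for algorithm cross-checks.
random_calibration <- function(seed, n = 12, p = 8) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rnorm(p)) + rnorm(n, sd = 0.3)
  list(X = X, y = y)
}

# Subset helper mirroring the package's internal split-by-set step.
spectra_subset <- function(sp, idx) {
  spectra_set(sp$wavelengths, sp$absorbance[idx, , drop = FALSE],
              sp$sample_ids[idx])
}
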