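# SIMPLS PLS1 regression with leave-one-out cross-validation and
# Haaland-Thomas latent-variable selection.

# Core SIMPLS recursion on a centred X / centred y. Returns weight matrix R
# (so scores T = Xc %*% R), loadings P, y-loadings q, and regression vectors
# B[, h] for every truncation level 1..max_lv.
simpls_core <- function(Xc, yc, max_lv) {
  p <- ncol(Xc)
  s <- drop(crossprod(Xc, yc))
  R <- matrix(0, p, max_lv); P <- matrix(0, p, max_lv)
  Tm <- matrix(0, nrow(Xc), max_lv); q <- numeric(max_lv)
  V <- matrix(0, p, max_lv)
  achieved <- max_lv
  nt1 <- NULL
  for (a in seq_len(max_lv)) {
    r <- s                                  # PLS1: weight direction = deflated covariance
    t <- drop(Xc %*% r)
    nt <- sqrt(sum(t^2))
    if (a == 1L) {
      if (nt < 1e-300) stop_mixcal("SIMPLS: y has no covariance with X")
      nt1 <- nt
    }
    if (nt < 1e-12 * nt1) {
      # covariance exhausted: later components carry nothing; regression
      # vectors beyond this point repeat the last informative one
      achieved <- a - 1L
      break
    }
    t <- t / nt; r <- r / nt
    pa <- drop(crossprod(Xc, t))
    q[a] <- sum(yc * t)
    v <- pa
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pa)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v * drop(crossprod(v, s))
    R[, a] <- r; P[, a] <- pa; Tm[, a] <- t; V[, a] <- v
  }
  B <- sapply(seq_len(max_lv), function(h) {
    hh <- min(h, achieved)
    drop(R[, seq_len(hh), drop = FALSE] %*% q[seq_len(hh)])
  })
  list(R = R, P = P, T = Tm, q = q, B = matrix(B, nrow = p),
       achieved = achieved)
}

#' Fit a SIMPLS PLS1 calibration model
#'
#' Direct SIMPLS recursion for a single response: the covariance vector
#' `s = X'y` supplies each weight, scores are `t = X w` (unit length),
#' loadings `p = X't`, and `s` is deflated by projection onto the
#' orthonormalized loading basis. Regression vectors are kept for every
#' truncation level `1..max_lv`. X and y are centred internally; the
#' intercept restores the original scale at prediction time.
#'
#' @param spectra Preprocessed calibration [spectra_set] (or numeric matrix).
#' @param y Concentration vector, one value per sample; must vary.
#' @param max_lv Maximum latent variables, `<= min(n - 1, p)`. Default 10, a
#'   sensible ceiling for 25-sample calibration designs.
#' @param run_cv If `TRUE` (default) attach the leave-one-out PRESS/RMSECV
#'   curve and a Haaland-Thomas choice of `n_lv`.
#' @param alpha Haaland-Thomas F-test level, see [select_lv_haaland()].
#' @return Object of class `pls_model`: weights/scores/loadings, regression
#'   vectors per LV, `x_center`, `y_center`, and (if `run_cv`) `press`,
#'   `rmsecv`, `n_lv`.
#' @export
simpls_fit <- function(spectra, y, max_lv = 10, run_cv = TRUE, alpha = 0.25) {
  X <- if (inherits(spectra, "spectra_set")) spectra$absorbance else as.matrix(spectra)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_mixcal("length(y) must equal the number of spectra")
  if (stats::sd(y) == 0) stop_mixcal("y has zero variance")
  if (max_lv > min(n - 1L, p)) {
    stop_mixcal(sprintf("max_lv = %d exceeds min(n - 1, p) = %d",
                        max_lv, min(n - 1L, p)))
  }
  x_center <- colMeans(X); y_center <- mean(y)
  core <- simpls_core(sweep(X, 2, x_center), y - y_center, max_lv)
  fit <- structure(
    list(weights = core$R, loadings = core$P, scores = core$T,
         y_loadings = core$q, coefficients = core$B,
         achieved = core$achieved,
         x_center = x_center, y_center = y_center,
         max_lv = max_lv, n = n, n_lv = max_lv,
         press = NULL, rmsecv = NULL),
    class = "pls_model"
  )
  if (run_cv && n >= 3L) {
    cv <- loo_rmsecv(X, y, max_lv)
    fit$press <- cv$press
    fit$rmsecv <- cv$rmsecv
    sel <- select_lv_haaland(cv$press, n, alpha)
    fit$n_lv <- sel$n_lv
    fit$lv_ratio_trace <- sel$ratio
  }
  fit
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d samples x %d wavelengths, max %d LVs, chosen n_lv = %d>\n",
              x$n, nrow(x$coefficients), x$max_lv, x$n_lv))
  if (!is.null(x$rmsecv)) {
    cat("  RMSECV:", paste(sprintf("%.4g", x$rmsecv), collapse = " "), "\n")
  }
  invisible(x)
}

#' Predict concentrations from a SIMPLS model
#'
#' `yhat = (X_new - x_center) %*% b(n_lv) + y_center`; `n_lv = 0` returns the
#' training mean for every sample.
#'
#' @param model A `pls_model`.
#' @param spectra New [spectra_set] or matrix on the fitted wavelength axis.
#' @param n_lv Number of latent variables; default the model's chosen `n_lv`.
#' @return Numeric vector of predicted concentrations.
#' @export
pls_predict <- function(model, spectra, n_lv = model$n_lv) {
  stopifnot(inherits(model, "pls_model"))
  X <- if (inherits(spectra, "spectra_set")) spectra$absorbance else as.matrix(spectra)
  if (ncol(X) != length(model$x_center)) {
    stop_mixcal("wavelength count does not match the fitted model")
  }
  if (n_lv < 0 || n_lv > model$max_lv) {
    stop_mixcal("n_lv must be between 0 and the fitted max_lv")
  }
  if (n_lv == 0L) return(rep(model$y_center, nrow(X)))
  drop(sweep(X, 2, model$x_center) %*% model$coefficients[, n_lv]) + model$y_center
}

#' Leave-one-out cross-validation PRESS / RMSECV per latent variable
#'
#' For each held-out sample the SIMPLS model is refitted on the remaining
#' n-1 samples and the held-out concentration predicted at every truncation
#' level; `RMSECV(h) = sqrt(PRESS(h) / n)`.
#'
#' @param X Calibration matrix or [spectra_set].
#' @param y Concentration vector.
#' @param max_lv Maximum latent variables (capped at `n - 2` inside the loop).
#' @return List with `press` and `rmsecv` vectors of length `max_lv` and
#'   `n_heldout` (= n).
#' @export
loo_rmsecv <- function(X, y, max_lv = 10) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop_mixcal("leave-one-out needs at least 3 samples")
  max_lv <- min(max_lv, n - 2L, ncol(X))
  press <- numeric(max_lv)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    xc <- colMeans(Xi); yc <- mean(yi)
    core <- simpls_core(sweep(Xi, 2, xc), yi - yc, max_lv)
    pred <- drop((X[i, ] - xc) %*% core$B) + yc
    press <- press + (pred - y[i])^2
  }
  list(press = press, rmsecv = sqrt(press / n), n_heldout = n)
}

#' Haaland-Thomas selection of the number of latent variables
#'
#' Picks the most parsimonious model whose PRESS is statistically
#' indistinguishable from the minimum: with `h* = argmin PRESS`, the chosen
#' rank is the smallest `h` with `PRESS(h)/PRESS(h*) <= qf(1 - alpha, n, n)`.
#'
#' @param press_curve PRESS per latent variable (finite, non-empty).
#' @param n Number of cross-validated samples.
#' @param alpha F-test level; default 0.25, the method's convention.
#' @return List with `n_lv`, `h_min`, and the `ratio` trace
#'   `PRESS(h)/PRESS(h*)`.
#' @export
select_lv_haaland <- function(press_curve, n, alpha = 0.25) {
  press_curve <- as.numeric(press_curve)
  if (length(press_curve) == 0L || any(!is.finite(press_curve))) {
    stop_mixcal("PRESS curve must be non-empty and finite")
  }
  h_min <- which.min(press_curve)
  ratio <- press_curve / press_curve[h_min]
  fcrit <- stats::qf(1 - alpha, n, n)
  list(n_lv = which(ratio <= fcrit)[1], h_min = h_min, ratio = ratio)
}

#' Compress spectra to PCA or PLS scores
#'
#' Builds a low-dimensional score representation for downstream regressors:
#' PCA scores are the first `k` left singular vectors times singular values of
#' the centred matrix; PLS scores are the first `k` SIMPLS scores (which
#' require `y`). The fitted basis projects new spectra onto the same scores.
#'
#' @param spectra Calibration [spectra_set] or matrix.
#' @param y Concentration vector (required for `method = "PLS"`).
#' @param k Number of scores, `1 <= k <= rank`.
#' @param method `"PCA"` or `"PLS"`.
#' @return Object of class `score_matrix`: `scores` (n x k), `method`, `k`,
#'   plus the projection basis. Use [compress_project()] for new spectra.
#' @export
compress <- function(spectra, y = NULL, k, method = c("PCA", "PLS")) {
  method <- match.arg(method)
  X <- if (inherits(spectra, "spectra_set")) spectra$absorbance else as.matrix(spectra)
  if (k < 1) stop_mixcal("k must be >= 1")
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  if (method == "PCA") {
    sv <- svd(Xc)
    rank <- sum(sv$d > sv$d[1] * 1e-10)
    if (k > rank) stop_mixcal(sprintf("k = %d exceeds the matrix rank %d", k, rank))
    scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
    basis <- sv$v[, seq_len(k), drop = FALSE]
  } else {
    if (is.null(y)) stop_mixcal("PLS compression requires y")
    if (k > min(nrow(X) - 1L, ncol(X))) stop_mixcal("k exceeds the usable PLS rank")
    core <- simpls_core(Xc, as.numeric(y) - mean(y), k)
    if (core$achieved < k) stop_mixcal("k exceeds the usable PLS rank")
    scores <- core$T
    basis <- core$R
  }
  colnames(scores) <- paste0(method, seq_len(k))
  structure(list(scores = scores, method = method, k = k,
                 x_center = x_center, basis = basis),
            class = "score_matrix")
}

#' Project new spectra onto a fitted compression basis
#'
#' @param sm A `score_matrix` from [compress()].
#' @param spectra New [spectra_set] or matrix on the same wavelength axis.
#' @return n_new x k score matrix.
#' @export
compress_project <- function(sm, spectra) {
  stopifnot(inherits(sm, "score_matrix"))
  X <- if (inherits(spectra, "spectra_set")) spectra$absorbance else as.matrix(spectra)
  if (ncol(X) != length(sm$x_center)) stop_mixcal("wavelength count mismatch")
  out <- sweep(X, 2, sm$x_center) %*% sm$basis
  colnames(out) <- colnames(sm$scores)
  out
}

#' Serialize / restore a fitted PLS model as JSON
#'
#' @param model A `pls_model`.
#' @param path File path.
#' @name pls_io
#' @export
write_pls_json <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pls_io
#' @export
read_pls_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("weights", "loadings", "scores", "coefficients")) {
    x[[nm]] <- as.matrix(x[[nm]])
  }
  structure(x, class = "pls_model")
}
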