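# Wavelength-band selection and fit/apply spectral preprocessing.
# Every transform fitted on calibration spectra returns a `preprocessor_state`
# whose apply step is deterministic, so states fitted on the calibration set
# can be replayed on stability/test spectra without leakage.

#' Define a wavelength band selection
#'
#' @param ... Two-element numeric vectors `c(start_nm, stop_nm)`, inclusive
#'   endpoints. Intervals must not overlap; they are sorted by start.
#' @return Object of class `band_selection`.
#' @export
band_selection <- function(...) {
  bands <- list(...)
  if (length(bands) == 1L && is.list(bands[[1]]) && !is.numeric(bands[[1]])) {
    bands <- bands[[1]]
  }
  bands <- lapply(bands, as.numeric)
  if (length(bands) == 0L) stop_mixcal("at least one band is required")
  for (b in bands) {
    if (length(b) != 2L || !all(is.finite(b))) {
      stop_mixcal("each band must be c(start_nm, stop_nm)")
    }
    if (b[1] >= b[2]) stop_mixcal("band start must be < stop")
  }
  bands <- bands[order(vapply(bands, `[`, 0, 1))]
  starts <- vapply(bands, `[`, 0, 1); stops <- vapply(bands, `[`, 0, 2)
  if (any(starts[-1] <= stops[-length(stops)])) {
    stop_mixcal("bands must be non-overlapping")
  }
  structure(bands, class = "band_selection")
}

#' Preset analyte band selections
#'
#' The knowledge-based wavelength windows used for each analyte: ALG and PIO
#' use 230.5-245 nm plus 260-300 nm (111 grid points at 0.5 nm); GLM uses
#' 230.5-245 nm plus 300.5-380 nm (190 points), where its broad long-wave
#' band is free of ALG/PIO interference.
#'
#' @param analyte `"ALG"`, `"PIO"` or `"GLM"`.
#' @return A [band_selection].
#' @export
analyte_bands <- function(analyte = c("ALG", "PIO", "GLM")) {
  analyte <- match.arg(analyte)
  if (analyte == "GLM") {
    band_selection(c(230.5, 245), c(300.5, 380))
  } else {
    band_selection(c(230.5, 245), c(260, 300))
  }
}

#' Restrict a spectra set to selected wavelength bands
#'
#' Keeps grid points with `start <= lambda <= stop` for any band (endpoints
#' inclusive), preserving order. Band endpoints must coincide with grid
#' points (within 1e-9 nm) and lie inside the grid span.
#'
#' @param spectra A [spectra_set].
#' @param bands A [band_selection].
#' @return A [spectra_set] on the reduced (piecewise-uniform) grid. The
#'   reduced wavelength axis is stored as-is; downstream modelling treats
#'   columns as features.
#' @export
select_bands <- function(spectra, bands) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (!inherits(bands, "band_selection")) bands <- band_selection(bands)
  wl <- spectra$wavelengths
  keep <- rep(FALSE, length(wl))
  for (b in bands) {
    if (b[1] < min(wl) - 1e-9 || b[2] > max(wl) + 1e-9) {
      stop_mixcal(sprintf("band %.1f-%.1f nm lies outside the grid span", b[1], b[2]))
    }
    if (min(abs(wl - b[1])) > 1e-9 || min(abs(wl - b[2])) > 1e-9) {
      stop_mixcal(sprintf("band endpoints %.2f/%.2f nm are off-grid", b[1], b[2]))
    }
    keep <- keep | (wl >= b[1] - 1e-9 & wl <= b[2] + 1e-9)
  }
  out <- spectra
  out$wavelengths <- wl[keep]
  out$absorbance <- spectra$absorbance[, keep, drop = FALSE]
  out
}

new_preprocessor_state <- function(method, params) {
  structure(list(method = method, params = params), class = "preprocessor_state")
}

#' @export
print.preprocessor_state <- function(x, ...) {
  cat(sprintf("<preprocessor_state: %s>\n", x$method)); invisible(x)
}

#' Fit and apply column centering / autoscaling
#'
#' `MC` subtracts calibration column means; `AS` additionally divides by
#' calibration column standard deviations (n-1 denominator). The fitted state
#' replays the calibration means/sds on new spectra.
#'
#' @param spectra Calibration [spectra_set] with >= 2 samples.
#' @param method `"MC"` or `"AS"`.
#' @return List with `state` ([`preprocessor_state`][preprocess_apply]) and
#'   `transformed` ([spectra_set]).
#' @export
fit_centering <- function(spectra, method = c("MC", "AS")) {
  method <- match.arg(method)
  stopifnot(inherits(spectra, "spectra_set"))
  X <- spectra$absorbance
  if (nrow(X) < 2L) stop_mixcal("centering requires at least 2 calibration samples")
  mu <- colMeans(X)
  sds <- NULL
  if (method == "AS") {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      bad <- spectra$wavelengths[which(sds == 0)[1]]
      stop_mixcal(sprintf("autoscale: zero-variance column at %.1f nm", bad))
    }
  }
  state <- new_preprocessor_state(method, list(
    wavelengths = spectra$wavelengths, means = mu, sds = sds))
  list(state = state, transformed = preprocess_apply(state, spectra))
}

#' Standard normal variate transform
#'
#' Row-wise standardization: each spectrum becomes
#' `(x - mean(x)) / sd(x)` (n-1 denominator). Stateless and idempotent.
#'
#' @param spectra A [spectra_set]; every row needs at least two distinct
#'   values.
#' @return Transformed [spectra_set].
#' @export
snv <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  X <- spectra$absorbance
  s <- apply(X, 1, stats::sd)
  if (any(s == 0)) stop_mixcal("SNV undefined for a constant spectrum (row sd = 0)")
  out <- spectra
  out$absorbance <- (X - rowMeans(X)) / s
  out
}

#' Fit multiplicative scatter correction
#'
#' The reference is the calibration mean spectrum. Each spectrum `x` is
#' regressed `x ~ a * ref + b` by ordinary least squares over the selected
#' wavelengths and corrected to `(x - b) / a`.
#'
#' @param spectra Calibration [spectra_set] with >= 2 samples.
#' @return List with `state` and `transformed` as in [fit_centering()].
#' @export
msc_fit <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (nrow(spectra$absorbance) < 2L) {
    stop_mixcal("MSC requires at least 2 calibration samples to form a reference")
  }
  ref <- colMeans(spectra$absorbance)
  state <- new_preprocessor_state("MSC", list(
    wavelengths = spectra$wavelengths, reference = ref))
  list(state = state, transformed = preprocess_apply(state, spectra))
}

msc_correct <- function(X, ref) {
  refc <- ref - mean(ref)
  den <- sum(refc^2)
  if (den < 1e-24) stop_mixcal("MSC reference has no variation")
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    a <- sum((x - mean(x)) * refc) / den
    if (abs(a) < 1e-12) stop_mixcal("MSC: fitted multiplicative slope is zero")
    b <- mean(x) - a * mean(ref)
    out[i, ] <- (x - b) / a
  }
  out
}

#' Fit orthogonal signal correction
#'
#' Removes from centred spectra the dominant variation orthogonal to the
#' response: per component the score starts at the first principal-component
#' score of X, then iterates (i) orthogonalize the score against `y`,
#' (ii) solve `X w = t` for the least-norm weight `w` (normalized),
#' (iii) recompute `t = X w`, until the relative score change drops below
#' `tol`. The removed score is re-orthogonalized against `y` before deflation
#' `X <- X - t p'` with loading `p = X't / (t't)`.
#'
#' @param spectra Centred calibration [spectra_set] (apply `MC` first).
#' @param y Response vector (one concentration per sample).
#' @param n_components Number of orthogonal components to remove; 0 gives an
#'   identity state.
#' @param tol Relative score-change convergence tolerance.
#' @param max_iter Maximum iterations per component; non-convergence errors
#'   with the iteration trace attached.
#' @return List with `state` (method `"OSC"`) and `transformed`.
#' @export
osc_fit <- function(spectra, y, n_components = 1, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(spectra, "spectra_set"))
  X <- spectra$absorbance
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop_mixcal("length(y) must equal the sample count")
  if (n_components < 0) stop_mixcal("n_components must be >= 0")
  if (max(abs(colMeans(X))) > 1e-6 * max(1, max(abs(X)))) {
    stop_mixcal("OSC expects mean-centred spectra; apply MC first")
  }
  if (n_components >= 1 && sum(X^2) < 1e-24) {
    stop_mixcal("OSC: spectra have no variance")
  }
  weights <- list(); loadings <- list()
  yc <- y - mean(y)                     # scores of centred X are mean-free,
  yy <- sum(yc^2)                       # so orthogonality is against centred y
  if (yy == 0) stop_mixcal("OSC: y has no variance")
  for (comp in seq_len(n_components)) {
    Xp <- svd(X)                        # reused for the least-norm solves
    pos <- Xp$d > Xp$d[1] * 1e-12
    U <- Xp$u[, pos, drop = FALSE]
    t_cur <- Xp$u[, 1] * Xp$d[1]
    # The iteration below is a power method whose fixed point is the
    # projection of the initial score onto col(X) inter y-perp; start there
    # so the loop converges immediately instead of grinding through the
    # slow mode along the in-space direction closest to y.
    uy <- drop(U %*% crossprod(U, yc))
    if (sqrt(sum(uy^2)) > 1e-12 * sqrt(yy)) {
      u_star <- uy / sqrt(sum(uy^2))
      t_cur <- t_cur - u_star * sum(u_star * t_cur)
    }
    if (sqrt(sum(t_cur^2)) < 1e-10 * Xp$d[1]) {
      # no y-orthogonal variation to remove: store an explicit null component
      weights[[comp]] <- rep(0, ncol(X))
      loadings[[comp]] <- rep(0, ncol(X))
      next
    }
    trace <- numeric(0)
    converged <- FALSE
    w <- NULL
    t_hat <- t_cur / sqrt(sum(t_cur^2))
    for (it in seq_len(max_iter)) {
      t_orth <- t_hat - yc * (sum(yc * t_hat) / yy)
      # least-norm w solving X w = t_orth via the pseudoinverse
      w <- Xp$v[, pos, drop = FALSE] %*%
        ((crossprod(U, t_orth)) / Xp$d[pos])
      w <- drop(w) / sqrt(sum(w^2))
      t_new <- drop(X %*% w)
      t_new_hat <- t_new / sqrt(sum(t_new^2))
      if (sum(t_new_hat * t_hat) < 0) {
        t_new_hat <- -t_new_hat
        w <- -w
      }
      delta <- sqrt(sum((t_new_hat - t_hat)^2))
      trace <- c(trace, delta)
      t_hat <- t_new_hat
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      e <- simpleError(sprintf(
        "OSC component %d did not converge in %d iterations (last delta %.3g)",
        comp, max_iter, trace[length(trace)]))
      e$trace <- trace
      stop(e)
    }
    t_fin <- drop(X %*% w)
    t_rm <- t_fin - yc * (sum(yc * t_fin) / yy)  # removed score, exactly y-orthogonal
    p <- drop(crossprod(X, t_rm)) / sum(t_rm^2)
    X <- X - tcrossprod(t_rm, p)
    weights[[comp]] <- w
    loadings[[comp]] <- p
  }
  state <- new_preprocessor_state("OSC", list(
    wavelengths = spectra$wavelengths, weights = weights, loadings = loadings))
  transformed <- spectra
  transformed$absorbance <- X
  list(state = state, transformed = transformed)
}

#' Apply a fitted preprocessing state to new spectra
#'
#' Replays calibration-fitted parameters: MC/AS use stored means/sds, MSC the
#' stored reference, OSC filters each new spectrum with the stored
#' weight/loading pairs (`t = X w`, `X <- X - t p'`).
#'
#' @param state A `preprocessor_state` from [fit_centering()], [msc_fit()] or
#'   [osc_fit()].
#' @param spectra A [spectra_set] on the same wavelength axis.
#' @return Transformed [spectra_set].
#' @export
preprocess_apply <- function(state, spectra) {
  stopifnot(inherits(state, "preprocessor_state"), inherits(spectra, "spectra_set"))
  if (length(state$params$wavelengths) != length(spectra$wavelengths) ||
      max(abs(state$params$wavelengths - spectra$wavelengths)) > 1e-9) {
    stop_mixcal("wavelength axis does not match the fitted state")
  }
  X <- spectra$absorbance
  out <- spectra
  p <- state$params
  out$absorbance <- switch(state$method,
    MC = sweep(X, 2, p$means),
    AS = sweep(sweep(X, 2, p$means), 2, p$sds, "/"),
    MSC = msc_correct(X, p$reference),
    OSC = {
      for (i in seq_along(p$weights)) {
        t_new <- drop(X %*% p$weights[[i]])
        X <- X - tcrossprod(t_new, p$loadings[[i]])
      }
      X
    },
    stop_mixcal("unknown preprocessing method: ", state$method)
  )
  out
}

#' Serialize / restore a preprocessor state as JSON
#'
#' Portable representation (method tag + numeric parameter arrays) so a
#' fitted pipeline can be replayed elsewhere.
#'
#' @param state A `preprocessor_state`.
#' @param path File path.
#' @return `read_preprocessor_json` returns the restored state.
#' @name preprocessor_io
#' @export
write_preprocessor_json <- function(state, path) {
  stopifnot(inherits(state, "preprocessor_state"))
  jsonlite::write_json(list(method = state$method, params = state$params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname preprocessor_io
#' @export
read_preprocessor_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- x$params
  p$wavelengths <- as.numeric(p$wavelengths)
  for (nm in intersect(c("means", "sds", "reference"), names(p))) {
    p[[nm]] <- as.numeric(p[[nm]])
  }
  for (nm in intersect(c("weights", "loadings"), names(p))) {
    if (is.matrix(p[[nm]])) {
      p[[nm]] <- lapply(seq_len(nrow(p[[nm]])), function(i) p[[nm]][i, ])
    } else {
      p[[nm]] <- lapply(p[[nm]], as.numeric)
    }
  }
  new_preprocessor_state(x$method, p)
}
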