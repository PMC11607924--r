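# Broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a spectra set into long format
#'
#' @param x A [spectra_set].
#' @param ... Unused.
#' @return Tibble: `sample_id`, `wavelength_nm`, `absorbance`.
#' @export
tidy.spectra_set <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$sample_ids, each = length(x$wavelengths)),
    wavelength_nm = rep(x$wavelengths, times = length(x$sample_ids)),
    absorbance = as.vector(t(x$absorbance)))
}

#' Tidy / summarize a SIMPLS model
#'
#' `tidy()` returns the cross-validation curve (one row per latent variable);
#' `glance()` a one-row model summary.
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pls_model <- function(x, ...) {
  if (is.null(x$press)) {
    return(tibble::tibble(lv = seq_len(x$max_lv), press = NA_real_,
                          rmsecv = NA_real_))
  }
  tibble::tibble(lv = seq_along(x$press), press = x$press, rmsecv = x$rmsecv)
}

#' @rdname tidy.pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(n = x$n, max_lv = x$max_lv, n_lv = x$n_lv,
                 rmsecv = if (is.null(x$rmsecv)) NA_real_ else x$rmsecv[x$n_lv])
}

#' Tidy / summarize a gradient-boosted tree model
#'
#' `tidy()` returns the training-loss trace per boosting round; `glance()` a
#' one-row summary.
#'
#' @param x A `gbt_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gbt_model <- function(x, ...) {
  tibble::tibble(round = seq_along(x$loss_trace), train_mse = x$loss_trace)
}

#' @rdname tidy.gbt_model
#' @export
glance.gbt_model <- function(x, ...) {
  n_leaves <- function(node) {
    if (node$leaf) 1L else n_leaves(node$left) + n_leaves(node$right)
  }
  tibble::tibble(
    num_round = length(x$trees), eta = x$cfg$eta, max_depth = x$cfg$max_depth,
    lambda = x$cfg$lambda, mean_leaves = mean(vapply(x$trees, n_leaves, 0L)),
    final_train_mse = x$loss_trace[length(x$loss_trace)])
}

#' Tidy / summarize a backprop network fit
#'
#' `tidy()` returns per-epoch training (and, when monitored, monitor) RMSEP;
#' `glance()` a one-row summary.
#'
#' @param x An `ann_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ann_model <- function(x, ...) {
  out <- tibble::tibble(epoch = seq_along(x$train_trace),
                        train_rmsep = x$train_trace)
  if (!is.null(x$monitor_trace)) out$monitor_rmsep <- x$monitor_trace
  out
}

#' @rdname tidy.ann_model
#' @export
glance.ann_model <- function(x, ...) {
  tibble::tibble(hidden = x$cfg$hidden, learning_rate = x$cfg$learning_rate,
                 stopped_epoch = x$stopped_epoch,
                 final_train_rmsep = x$train_trace[length(x$train_trace)],
                 best_monitor_rmsep = if (is.null(x$monitor_trace)) NA_real_
                 else min(x$monitor_trace))
}

#' Summarize a fitted nu-SVR model
#'
#' @param x An `svr_model`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.svr_model <- function(x, ...) {
  tibble::tibble(cost = x$cfg$cost, nu = x$cfg$nu, gamma = x$cfg$gamma,
                 n_support_vectors = x$fit$tot.nSV)
}

#' Tidy design diagnostics
#'
#' `tidy()` returns the principal-component scores of the mean-centred
#' concentration matrix; `glance()` the orthogonality summary.
#'
#' @param x A `design_diagnostics` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.design_diagnostics <- function(x, ...) x$scores

#' @rdname tidy.design_diagnostics
#' @export
glance.design_diagnostics <- function(x, ...) {
  off <- x$correlations[upper.tri(x$correlations)]
  tibble::tibble(n_factors = length(x$means),
                 max_abs_correlation = max(abs(off)),
                 n_outside_hull = if (is.null(x$outside_hull)) NA_integer_
                 else sum(x$outside_hull))
}

#' Tidy a pipeline result
#'
#' `tidy()` returns the per-model/analyte report; `glance()` one row with the
#' run provenance.
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pipeline_result <- function(x, ...) x$report

#' @rdname tidy.pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(seed = x$seed, config_hash = x$config_hash,
                 n_fits = nrow(x$report))
}
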