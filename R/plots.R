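# ggplot2 visualizations for spectra, designs, model selection curves and the
# model comparison bars.

#' Overlay plot of spectra
#'
#' @param object A [spectra_set].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectra_set <- function(object, ...) {
  df <- tidy.spectra_set(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$absorbance,
                                   group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Absorbance (AU)") +
    ggplot2::theme_minimal()
}

#' Design scores plot
#'
#' PC1 vs PC2 of the mean-centred concentration matrix, coloured by set: the
#' standard check that calibration points cover the mixture space
#' symmetrically and that test points sit inside it.
#'
#' @param object A `design_diagnostics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.design_diagnostics <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$set)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "Set") +
    ggplot2::theme_minimal()
}

#' Cross-validation curve of a SIMPLS model
#'
#' RMSECV against the number of latent variables, with the chosen rank marked.
#'
#' @param object A `pls_model` fitted with `run_cv = TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pls_model <- function(object, ...) {
  df <- tidy.pls_model(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lv, .data$rmsecv)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_lv, linetype = 2) +
    ggplot2::labs(x = "Latent variables", y = "RMSECV (ug/mL)") +
    ggplot2::theme_minimal()
}

#' Training-loss trace of a boosted-tree model
#'
#' @param object A `gbt_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gbt_model <- function(object, ...) {
  df <- tidy.gbt_model(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$round, .data$train_mse)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Boosting round", y = "Training MSE") +
    ggplot2::theme_minimal()
}

#' RMSEP / recovery-SD comparison bars
#'
#' Side-by-side bars per analyte and model for the test-set RMSEP and the
#' standard deviation of recoveries, the two headline comparison figures.
#'
#' @param report Report tibble (from `tidy()` on a `pipeline_result`, or
#'   [compare_models()] output).
#' @param metric `"rmsep"` or `"sd_recovery"`.
#' @return A ggplot.
#' @export
plot_model_comparison <- function(report, metric = c("rmsep", "sd_recovery")) {
  metric <- match.arg(metric)
  report <- tibble::as_tibble(report)
  ggplot2::ggplot(report,
                  ggplot2::aes(.data$analyte, .data[[metric]],
                               fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, fill = "Model",
                  y = if (metric == "rmsep") "RMSEP (ug/mL)"
                      else "SD of recoveries (%)") +
    ggplot2::theme_minimal()
}

#' Export plot-ready comparison data as CSV
#'
#' Long-format table (`analyte`, `model`, `metric`, `value`) for external
#' plotting of the RMSEP and recovery-SD comparison.
#'
#' @param report Report tibble.
#' @param path Output path.
#' @export
write_comparison_csv <- function(report, path) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(report)[, c("analyte", "model", "rmsep", "sd_recovery")],
    cols = c("rmsep", "sd_recovery"),
    names_to = "metric", values_to = "value")
  readr::write_csv(long, path)
  invisible(path)
}
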