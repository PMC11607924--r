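# Prediction-quality metrics and model comparison.

#' Recovery percentages
#'
#' `recovery_i = 100 * predicted_i / nominal_i`; undefined (an error) when any
#' nominal concentration is zero.
#'
#' @param predicted,nominal Equal-length numeric vectors (ug/mL).
#' @return Numeric vector of recoveries in percent.
#' @export
recovery <- function(predicted, nominal) {
  predicted <- as.numeric(predicted); nominal <- as.numeric(nominal)
  if (length(predicted) != length(nominal)) stop_mixcal("length mismatch")
  if (any(nominal == 0)) {
    stop_mixcal("recovery is undefined for zero nominal concentrations")
  }
  100 * predicted / nominal
}

#' Summarize recoveries as mean and standard deviation
#'
#' The assay-table convention: arithmetic mean and n-1 standard deviation of
#' the per-sample recovery percentages.
#'
#' @param recoveries Numeric vector of recovery percentages.
#' @return One-row tibble: `n`, `mean_recovery`, `sd_recovery`.
#' @export
recovery_summary <- function(recoveries) {
  recoveries <- as.numeric(recoveries)
  tibble::tibble(n = length(recoveries),
                 mean_recovery = mean(recoveries),
                 sd_recovery = stats::sd(recoveries))
}

#' Prediction metrics for one analyte / model
#'
#' Computes the standard external-validation record:
#' `RMSEP = sqrt(mean((yhat - y)^2))`, per-sample recovery percentages with
#' their mean and n-1 SD, `RPD = sd(y) / RMSEP` (so `RPD * RMSEP = sd(y)`
#' identically), and `R2 = 1 - sum((yhat - y)^2) / sum((y - mean(y))^2)`.
#'
#' @param predicted,nominal Equal-length vectors, length >= 2; nominal values
#'   must be non-zero for recoveries.
#' @return One-row tibble: `n`, `rmsep`, `mean_recovery`, `sd_recovery`,
#'   `rpd`, `r2`.
#' @export
metrics <- function(predicted, nominal) {
  predicted <- as.numeric(predicted); nominal <- as.numeric(nominal)
  if (length(predicted) != length(nominal)) stop_mixcal("length mismatch")
  if (length(predicted) < 2L) stop_mixcal("metrics need at least 2 samples")
  rmsep <- sqrt(mean((predicted - nominal)^2))
  rec <- recovery(predicted, nominal)
  tibble::tibble(
    n = length(predicted),
    rmsep = rmsep,
    mean_recovery = mean(rec),
    sd_recovery = stats::sd(rec),
    rpd = stats::sd(nominal) / rmsep,
    r2 = 1 - sum((predicted - nominal)^2) / sum((nominal - mean(nominal))^2)
  )
}

#' Rank models per analyte
#'
#' Orders models by RMSEP ascending within each analyte, breaking ties by the
#' recovery SD. The input rows must all refer to the same evaluation data
#' (equal `n` per analyte).
#'
#' @param report Tibble with at least `model`, `analyte`, `rmsep`,
#'   `sd_recovery`, `n` columns (an evaluation report or a row-bound set of
#'   them).
#' @return The report tibble with a `rank` column, sorted by analyte then
#'   rank; ready for bar plotting via [plot_model_comparison()].
#' @export
compare_models <- function(report) {
  report <- tibble::as_tibble(report)
  need <- c("model", "analyte", "rmsep", "sd_recovery")
  if (!all(need %in% names(report))) {
    stop_mixcal("report must have columns: ", paste(need, collapse = ", "))
  }
  if ("n" %in% names(report)) {
    bad <- dplyr::summarise(dplyr::group_by(report, .data$analyte),
                            distinct_n = dplyr::n_distinct(.data$n))
    if (any(bad$distinct_n > 1)) {
      stop_mixcal("models within an analyte were evaluated on different sets")
    }
  }
  out <- dplyr::arrange(report, .data$analyte, .data$rmsep, .data$sd_recovery)
  out <- dplyr::mutate(dplyr::group_by(out, .data$analyte),
                       rank = dplyr::row_number())
  dplyr::ungroup(out)
}
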