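# End-to-end pipeline: data -> set split -> per analyte/model band selection,
# preprocessing (fitted on calibration rows only), optional score
# compression, model fit, test-set prediction and metrics.

#' Pipeline configuration
#'
#' @param design Concentration design tibble (`sample_id`, `set`, analyte
#'   columns); default the packaged calibration/stability/test layout from
#'   [load_table1_fixture()].
#' @param components Pure-component library for simulation; default
#'   [default_components()].
#' @param distortion A [distortion_config()] controlling the simulated
#'   measurement distortions; its `seed` is overridden by `seed`.
#' @param presets Preset tibble (subset of [model_presets()]) naming the
#'   model x analyte combinations to run.
#' @param spectra_csv,concentrations_csv Optional paths; when both are given
#'   the spectra and concentrations are loaded instead of simulated.
#' @param seed Integer seed driving simulation and every stochastic fit.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = NULL, components = default_components(),
                            distortion = distortion_config(),
                            presets = model_presets(),
                            spectra_csv = NULL, concentrations_csv = NULL,
                            seed = 1L) {
  structure(list(design = design, components = components,
                 distortion = distortion, presets = tibble::as_tibble(presets),
                 spectra_csv = spectra_csv,
                 concentrations_csv = concentrations_csv,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_mixcal(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
  })
}

fit_chain <- function(chain, spectra_m, y_m) {
  states <- list()
  current <- spectra_m
  for (tag in chain) {
    if (tag == "SNV") {
      current <- snv(current)
      states[[length(states) + 1L]] <- "SNV"
      next
    }
    fitted <- switch(tag,
      MC = fit_centering(current, "MC"),
      AS = fit_centering(current, "AS"),
      MSC = msc_fit(current),
      OSC = osc_fit(current, y_m),
      stop_mixcal("unknown preprocessing tag: ", tag))
    states[[length(states) + 1L]] <- fitted$state
    current <- fitted$transformed
  }
  list(states = states, transformed = current)
}

apply_chain <- function(states, spectra) {
  for (st in states) {
    spectra <- if (identical(st, "SNV")) snv(spectra) else preprocess_apply(st, spectra)
  }
  spectra
}

fit_predict_one <- function(model, params, feats_m, y_m, feats_t, feats_st,
                            y_t = NULL, seed = 1L) {
  pred <- switch(model,
    pls = {
      fit <- simpls_fit(feats_m, y_m,
                        max_lv = min(params$max_lv %||% 10,
                                     nrow(feats_m$absorbance) - 2L,
                                     ncol(feats_m$absorbance)))
      n_lv <- params$n_lv
      if (is.null(n_lv) || is.na(n_lv)) n_lv <- fit$n_lv
      list(fit = fit,
           test = pls_predict(fit, feats_t, n_lv),
           st = if (!is.null(feats_st)) pls_predict(fit, feats_st, n_lv),
           rmsecv = fit$rmsecv[n_lv])
    },
    gbt = {
      cfg <- gbt_config(eta = params$eta, max_depth = params$max_depth,
                        num_round = params$num_round %||% 200,
                        lambda = params$lambda %||% 1, seed = seed)
      fit <- gbt_fit(feats_m, y_m, cfg)
      list(fit = fit, test = gbt_predict(fit, feats_t),
           st = if (!is.null(feats_st)) gbt_predict(fit, feats_st),
           rmsecv = NA_real_)
    },
    svr = {
      cfg <- svr_config(cost = params$cost, nu = params$nu %||% 0.5,
                        gamma = params$gamma)
      fit <- svr_fit(feats_m, y_m, cfg)
      list(fit = fit, test = svr_predict(fit, feats_t),
           st = if (!is.null(feats_st)) svr_predict(fit, feats_st),
           rmsecv = NA_real_)
    },
    ann = {
      cfg <- ann_config(hidden = params$hidden %||% 5,
                        learning_rate = params$learning_rate %||% 0.125,
                        seed = seed)
      fit <- ann_fit(feats_m, y_m, cfg, monitor_features = feats_t,
                     monitor_y = y_t)
      list(fit = fit, test = ann_predict(fit, feats_t),
           st = if (!is.null(feats_st)) ann_predict(fit, feats_st),
           rmsecv = NA_real_)
    },
    stop_mixcal("unknown model: ", model))
  pred
}

#' Run the full calibration / evaluation pipeline
#'
#' Simulates (or loads) the spectra for the configured design, splits rows by
#' set label (M = calibration, St = replicate stability checks, T = test),
#' and for every configured model x analyte: selects the analyte's wavelength
#' bands, fits the preprocessing chain on M rows only and replays it on
#' St/T rows, optionally compresses to scores, fits the model, predicts the
#' test set and computes [metrics()]. Stability rows yield the SD of their
#' replicate predictions, an intermediate-precision check. Any stage error
#' aborts with the stage name.
#'
#' @param cfg A [pipeline_config()].
#' @return Object of class `pipeline_result`: list with `report` (tibble: one
#'   row per model x analyte with metrics, `st_sd`, `rmsecv`, preprocessing
#'   chain), `predictions` (per-sample tibble), `config_hash`, `seed`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  cfg$distortion$seed <- cfg$seed
  data <- stage("data", {
    if (!is.null(cfg$spectra_csv) && !is.null(cfg$concentrations_csv)) {
      list(spectra = read_spectra_csv(cfg$spectra_csv),
           concentrations = read_concentrations_csv(cfg$concentrations_csv))
    } else {
      design <- cfg$design %||% load_table1_fixture()
      simulate_dataset(design, cfg$components, cfg$distortion)
    }
  })
  conc <- tibble::as_tibble(data$concentrations)
  if (!"set" %in% names(conc)) conc$set <- "M"
  sets <- split(seq_len(nrow(conc)), conc$set)
  if (is.null(sets$M) || is.null(sets$T)) {
    stop_mixcal("design must contain calibration (M) and test (T) rows")
  }
  subset_spectra <- function(sp, idx) {
    spectra_set(sp$wavelengths, sp$absorbance[idx, , drop = FALSE],
                sp$sample_ids[idx])
  }
  sp_m <- subset_spectra(data$spectra, sets$M)
  sp_t <- subset_spectra(data$spectra, sets$T)
  sp_st <- if (!is.null(sets$St)) subset_spectra(data$spectra, sets$St)

  rows <- list(); preds <- list()
  for (i in seq_len(nrow(cfg$presets))) {
    p <- cfg$presets[i, ]
    model <- p$model; analyte <- p$analyte
    label <- paste(model, analyte, sep = "-")
    chain <- p$preprocess[[1]]
    compression <- p$compression[[1]]
    params <- p$params[[1]]
    y_m <- conc[[analyte]][sets$M]
    y_t <- conc[[analyte]][sets$T]
    y_st <- if (!is.null(sets$St)) conc[[analyte]][sets$St]

    bands <- stage(paste0(label, ":bands"), analyte_bands(analyte))
    bm <- stage(paste0(label, ":bands"), select_bands(sp_m, bands))
    bt <- stage(paste0(label, ":bands"), select_bands(sp_t, bands))
    bst <- if (!is.null(sp_st)) stage(paste0(label, ":bands"),
                                      select_bands(sp_st, bands))

    pre <- stage(paste0(label, ":preprocess"), fit_chain(chain, bm, y_m))
    pm <- pre$transformed
    pt <- stage(paste0(label, ":preprocess"), apply_chain(pre$states, bt))
    pst <- if (!is.null(bst)) stage(paste0(label, ":preprocess"),
                                    apply_chain(pre$states, bst))

    if (!is.null(compression)) {
      sm <- stage(paste0(label, ":compress"),
                  compress(pm, y = y_m, k = compression$k,
                           method = compression$method))
      feats_m <- sm$scores
      feats_t <- compress_project(sm, pt)
      feats_st <- if (!is.null(pst)) compress_project(sm, pst)
      fitted <- stage(paste0(label, ":fit"),
                      fit_predict_one(model, params, feats_m, y_m, feats_t,
                                      feats_st, y_t, seed = cfg$seed))
    } else {
      fitted <- stage(paste0(label, ":fit"),
                      fit_predict_one(model, params, pm, y_m, pt, pst, y_t,
                                      seed = cfg$seed))
    }

    met <- stage(paste0(label, ":metrics"), metrics(fitted$test, y_t))
    rows[[label]] <- dplyr::bind_cols(
      tibble::tibble(model = model, analyte = analyte,
                     preprocess = paste(chain, collapse = "+"),
                     compression = if (is.null(compression)) "none" else
                       paste0(compression$method, compression$k)),
      met,
      tibble::tibble(
        st_sd = if (!is.null(fitted$st)) stats::sd(fitted$st) else NA_real_,
        rmsecv = fitted$rmsecv %||% NA_real_)
    )
    preds[[label]] <- tibble::tibble(
      model = model, analyte = analyte,
      sample_id = sp_t$sample_ids, set = "T",
      nominal = y_t, predicted = fitted$test)
  }
  structure(
    list(report = dplyr::bind_rows(rows),
         predictions = dplyr::bind_rows(preds),
         config_hash = rlang::hash(cfg),
         seed = cfg$seed),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: seed %d, config %s>\n", x$seed, x$config_hash))
  print(x$report)
  invisible(x)
}

#' Write an evaluation report bundle as byte-stable JSON
#'
#' Keys are sorted and floats rounded to 6 significant digits so that a rerun
#' with the same configuration and seed produces a byte-identical file.
#'
#' @param result A `pipeline_result`.
#' @param path Output path.
#' @export
write_report_json <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  round6 <- function(df) {
    df <- tibble::as_tibble(df)
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          ~ signif(.x, 6)))
    df <- df[, sort(names(df))]
    df
  }
  out <- list(config_hash = result$config_hash,
              predictions = round6(result$predictions),
              report = round6(result$report),
              seed = result$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
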