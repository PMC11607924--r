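# Shipped model x analyte presets: band windows, preprocessing chain, score
# compression and hyperparameters for each calibration model.

#' Shipped model presets per analyte
#'
#' One row per model x analyte combination the pipeline ships ready-made:
#'
#' * `pls` -- mean centering, Haaland-Thomas LV selection (`n_lv = NA` means
#'   auto-select; the three-component mixtures typically settle at 3 LVs).
#' * `ann` -- compressed scores as inputs: PCA with 4 scores for ALG, PLS with
#'   3 scores for PIO (PCA 4 for GLM, a package default since no preset is
#'   established for that combination); learning rate 0.125, single hidden
#'   layer.
#' * `svr` -- nu-SVR, RBF kernel, mean centering + orthogonal signal
#'   correction then PCA scores; `C = 100`, `gamma = 0.1` for ALG and PIO,
#'   `C = 31.623`, `gamma = 3.162` for GLM.
#' * `gbt` -- gradient-boosted trees; mean centering only for GLM, mean
#'   centering + OSC with PLS score compression for ALG and PIO; learning
#'   rates 0.5 (ALG), 0.1 (PIO), 0.3 (GLM) with maximum depths 6, 1 and 4
#'   respectively; 200 rounds (package default, configurable).
#'
#' @return Tibble with columns `model`, `analyte`, `preprocess` (list of
#'   chain tags in order), `compression` (list or `NULL`), `params` (list).
#' @export
model_presets <- function() {
  row <- function(model, analyte, preprocess, compression, params) {
    tibble::tibble(model = model, analyte = analyte,
                   preprocess = list(preprocess),
                   compression = list(compression), params = list(params))
  }
  dplyr::bind_rows(
    row("pls", "ALG", c("MC"), NULL, list(n_lv = NA, max_lv = 10)),
    row("pls", "PIO", c("MC"), NULL, list(n_lv = NA, max_lv = 10)),
    row("pls", "GLM", c("MC"), NULL, list(n_lv = NA, max_lv = 10)),
    row("ann", "ALG", c("MC"), list(method = "PCA", k = 4),
        list(hidden = 5, learning_rate = 0.125)),
    row("ann", "PIO", c("MC"), list(method = "PLS", k = 3),
        list(hidden = 5, learning_rate = 0.125)),
    row("ann", "GLM", c("MC"), list(method = "PCA", k = 4),
        list(hidden = 5, learning_rate = 0.125)),
    row("svr", "ALG", c("MC", "OSC"), list(method = "PCA", k = 4),
        list(cost = 100, gamma = 0.1, nu = 0.5)),
    row("svr", "PIO", c("MC", "OSC"), list(method = "PCA", k = 4),
        list(cost = 100, gamma = 0.1, nu = 0.5)),
    row("svr", "GLM", c("MC", "OSC"), list(method = "PCA", k = 4),
        list(cost = 31.623, gamma = 3.162, nu = 0.5)),
    row("gbt", "ALG", c("MC", "OSC"), list(method = "PLS", k = 3),
        list(eta = 0.5, max_depth = 6, num_round = 200)),
    row("gbt", "PIO", c("MC", "OSC"), list(method = "PLS", k = 3),
        list(eta = 0.1, max_depth = 1, num_round = 200)),
    row("gbt", "GLM", c("MC"), list(method = "PLS", k = 3),
        list(eta = 0.3, max_depth = 4, num_round = 200))
  )
}

#' Write the preset registry as JSON
#'
#' @param path Output path.
#' @param presets Preset tibble, default [model_presets()].
#' @export
write_presets_json <- function(path, presets = model_presets()) {
  reg <- purrr::pmap(presets, function(model, analyte, preprocess, compression,
                                       params) {
    list(model = model, analyte = analyte, preprocess = preprocess,
         compression = compression, params = params)
  })
  jsonlite::write_json(reg, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
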