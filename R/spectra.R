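#' Construct a spectra set
#'
#' A `spectra_set` holds a set of UV/Vis absorbance spectra measured on a
#' common wavelength grid: the predictor block of a multivariate calibration.
#' It is backed by a samples-by-wavelengths numeric matrix; use [tidy()] for a
#' long tibble view and [autoplot()] for an overlay plot.
#'
#' @param wavelengths Strictly increasing wavelength axis in nm (uniform for
#'   freshly scanned/simulated spectra; piecewise after band selection).
#' @param absorbance Numeric matrix, one row per sample, one column per
#'   wavelength. No missing values.
#' @param sample_ids Character labels, one per row.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, absorbance, sample_ids = NULL) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  if (nrow(absorbance) == 0L && is.null(sample_ids)) sample_ids <- character(0)
  sample_ids <- sample_ids %||% paste0("S", seq_len(nrow(absorbance)))
  if (length(wavelengths) != ncol(absorbance)) {
    stop_mixcal("length(wavelengths) must equal ncol(absorbance)")
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop_mixcal("wavelength grid must be strictly increasing")
  }
  if (length(sample_ids) != nrow(absorbance)) {
    stop_mixcal("one sample_id per spectrum is required")
  }
  if (anyNA(absorbance)) stop_mixcal("absorbance matrix contains missing values")
  storage.mode(absorbance) <- "double"
  dimnames(absorbance) <- list(as.character(sample_ids), NULL)
  structure(
    list(wavelengths = wavelengths, absorbance = absorbance,
         sample_ids = as.character(sample_ids)),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set: %d spectra x %d wavelengths (%.1f-%.1f nm)>\n",
              nrow(x$absorbance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' The standard 200-400 nm scanning grid
#'
#' 200.0 to 400.0 nm inclusive at 0.5 nm resolution: 401 points, the scan
#' settings this pipeline is built around.
#' @return Numeric vector of wavelengths (nm).
#' @export
default_grid <- function() seq(200, 400, by = 0.5)

#' Define a pure analyte as a sum of Gaussian absorption bands
#'
#' @param name Analyte identifier, e.g. `"ALG"`.
#' @param bands Data frame with columns `center_nm`, `width_nm` (Gaussian
#'   standard deviation, nm) and `peak_absorptivity` (absorbance units per
#'   ug/mL at the band centre). At least one band; widths > 0,
#'   absorptivities >= 0.
#' @return An object of class `pure_component`.
#' @export
pure_component <- function(name, bands) {
  bands <- tibble::as_tibble(bands)
  need <- c("center_nm", "width_nm", "peak_absorptivity")
  if (!all(need %in% names(bands))) {
    stop_mixcal("bands must have columns center_nm, width_nm, peak_absorptivity")
  }
  if (nrow(bands) < 1L) stop_mixcal("a pure component needs at least one band")
  if (any(bands$width_nm <= 0)) stop_mixcal("band widths must be > 0")
  if (any(bands$peak_absorptivity < 0)) stop_mixcal("absorptivities must be >= 0")
  structure(list(name = as.character(name), bands = bands),
            class = "pure_component")
}

#' Default synthetic pure-component library
#'
#' Three synthetic pure spectra chosen to emulate the spectral regime of the
#' pioglitazone / alogliptin / glimepiride ternary mixture: ALG and PIO carry
#' strong, heavily overlapping bands across 235-285 nm, while GLM has one weak
#' band near 235 nm plus a broad low-absorptivity band in 300-360 nm, so that
#' at the design-centre concentrations (PIO 30, ALG 25, GLM 4 ug/mL) GLM
#' contributes only a few percent of the total absorbance below 300 nm but
#' dominates above it. These are synthetic stand-ins, not measured molar
#' absorptivities.
#'
#' @return Named list of [pure_component] objects (`ALG`, `PIO`, `GLM`).
#' @export
default_components <- function() {
  list(
    ALG = pure_component("ALG", data.frame(
      center_nm = c(238, 273), width_nm = c(9, 14),
      peak_absorptivity = c(0.030, 0.026))),
    PIO = pure_component("PIO", data.frame(
      center_nm = c(242, 266), width_nm = c(10, 12),
      peak_absorptivity = c(0.028, 0.030))),
    GLM = pure_component("GLM", data.frame(
      center_nm = c(235, 330), width_nm = c(8, 28),
      peak_absorptivity = c(0.012, 0.008)))
  )
}

#' Evaluate a pure-component absorptivity spectrum on a grid
#'
#' Sums the component's Gaussian bands pointwise:
#' `a(lambda) = sum_b peak_b * exp(-(lambda - center_b)^2 / (2 width_b^2))`,
#' in absorbance units per ug/mL.
#'
#' @param component A [pure_component].
#' @param grid Uniform wavelength grid within 200-400 nm.
#' @return Numeric absorptivity vector, one value per grid point.
#' @export
pure_spectrum <- function(component, grid = default_grid()) {
  if (!inherits(component, "pure_component")) {
    stop_mixcal("`component` must be a pure_component")
  }
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop_mixcal("wavelength grid is empty")
  if (!is_uniform_grid(grid)) stop_mixcal("wavelength grid must be uniform and increasing")
  if (min(grid) < 200 - 1e-9 || max(grid) > 400 + 1e-9) {
    stop_mixcal("grid must lie within 200-400 nm")
  }
  b <- component$bands
  out <- numeric(length(grid))
  for (i in seq_len(nrow(b))) {
    out <- out + b$peak_absorptivity[i] *
      exp(-((grid - b$center_nm[i])^2) / (2 * b$width_nm[i]^2))
  }
  out
}

#' Mix pure components under the Beer-Lambert law
#'
#' Absorbance is exactly linear in concentration:
#' `A = C %*% S` where `C` is the samples-by-analytes concentration matrix
#' (ug/mL) and `S` the analytes-by-wavelengths pure absorptivity matrix.
#'
#' @param components Named list of [pure_component]s.
#' @param concentrations Data frame with optional `sample_id` column and one
#'   numeric column per analyte (ug/mL), names matching `components`.
#' @param grid Wavelength grid.
#' @return A [spectra_set].
#' @export
mix_beer_lambert <- function(components, concentrations, grid = default_grid()) {
  conc <- tibble::as_tibble(concentrations)
  ids <- if ("sample_id" %in% names(conc)) as.character(conc$sample_id) else NULL
  conc <- conc[, setdiff(names(conc), c("sample_id", "set")), drop = FALSE]
  if (!setequal(names(conc), names(components))) {
    stop_mixcal("concentration columns must match component names: ",
                paste(names(components), collapse = ", "))
  }
  conc <- conc[, names(components), drop = FALSE]
  cmat <- as.matrix(conc)
  if (nrow(cmat) > 0 && any(cmat < 0)) stop_mixcal("concentrations must be non-negative")
  S <- do.call(rbind, lapply(components, pure_spectrum, grid = grid))
  A <- cmat %*% S
  spectra_set(grid, A, ids %||% paste0("S", seq_len(nrow(A))))
}

#' Distortion configuration for synthetic spectra
#'
#' Parameters of the non-ideal measurement model applied on top of the
#' Beer-Lambert mixture: detector saturation `A -> A / (1 + k A)` (the
#' non-linearity mechanism; `k = 0` recovers exact linearity), per-sample
#' multiplicative/additive scatter, a linear baseline drift across the grid
#' span, and i.i.d. Gaussian noise. All draws are reproducible from `seed`
#' through an independent sub-stream per sample.
#'
#' @param saturation_k Dimensionless saturation strength, >= 0.
#' @param scatter_slope_sd SD of the per-sample multiplicative slope around 1.
#' @param scatter_offset_sd SD of the per-sample additive offset (AU).
#' @param baseline_drift_sd SD of the drift accumulated across the full grid
#'   span (AU).
#' @param noise_sd SD of i.i.d. measurement noise (AU). Default 0.002 AU, a
#'   mild photometric noise level for a benchtop double-beam instrument.
#' @param seed Integer seed driving all random draws.
#' @return An object of class `distortion_config`.
#' @export
distortion_config <- function(saturation_k = 0, scatter_slope_sd = 0,
                              scatter_offset_sd = 0, baseline_drift_sd = 0,
                              noise_sd = 0.002, seed = 1L) {
  assert_scalar_number(saturation_k, "saturation_k", min = 0)
  assert_scalar_number(scatter_slope_sd, "scatter_slope_sd", min = 0)
  assert_scalar_number(scatter_offset_sd, "scatter_offset_sd", min = 0)
  assert_scalar_number(baseline_drift_sd, "baseline_drift_sd", min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  structure(list(saturation_k = saturation_k,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 baseline_drift_sd = baseline_drift_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "distortion_config")
}

#' Apply measurement distortions to a spectra set
#'
#' Per sample, in order: saturation `A/(1 + kA)`; multiplicative slope drawn
#' `N(1, scatter_slope_sd^2)` and additive offset `N(0, scatter_offset_sd^2)`;
#' linear baseline drift with endpoint magnitude drawn
#' `N(0, baseline_drift_sd^2)` ramped over the grid span; i.i.d. Gaussian
#' noise with SD `noise_sd`. Deterministic given `cfg$seed`.
#'
#' @param spectra A [spectra_set].
#' @param cfg A [distortion_config].
#' @return A distorted [spectra_set].
#' @export
distort <- function(spectra, cfg = distortion_config()) {
  stopifnot(inherits(spectra, "spectra_set"), inherits(cfg, "distortion_config"))
  A <- spectra$absorbance
  if (nrow(A) == 0L) return(spectra)
  wl <- spectra$wavelengths
  ramp <- if (length(wl) > 1L) (wl - wl[1]) / (wl[length(wl)] - wl[1]) else 0
  for (i in seq_len(nrow(A))) {
    a <- A[i, ]
    if (cfg$saturation_k > 0) a <- a / (1 + cfg$saturation_k * a)
    draws <- with_substream(cfg$seed, i, {
      list(slope = rnorm(1, 1, cfg$scatter_slope_sd),
           offset = rnorm(1, 0, cfg$scatter_offset_sd),
           drift = rnorm(1, 0, cfg$baseline_drift_sd),
           noise = rnorm(length(a), 0, cfg$noise_sd))
    })
    a <- a * draws$slope + draws$offset + draws$drift * ramp + draws$noise
    A[i, ] <- a
  }
  spectra_set(wl, A, spectra$sample_ids)
}

#' Simulate a full spectra + concentration dataset from a design
#'
#' Generates one spectrum per design row on the given grid (default the
#' 401-point 200-400 nm scan) by Beer-Lambert mixing of `components` followed
#' by [distort()].
#'
#' @param design Concentration design tibble with `sample_id`, optional `set`,
#'   and one concentration column per analyte (ug/mL), as produced by
#'   [map_levels()] or [load_table1_fixture()].
#' @param components Named list of [pure_component]s; default
#'   [default_components()].
#' @param cfg A [distortion_config].
#' @param grid Wavelength grid.
#' @return List with elements `spectra` ([spectra_set]) and `concentrations`
#'   (tibble `sample_id`, optional `set`, analyte columns).
#' @export
simulate_dataset <- function(design, components = default_components(),
                             cfg = distortion_config(), grid = default_grid()) {
  design <- tibble::as_tibble(design)
  if (!"sample_id" %in% names(design)) {
    design <- tibble::add_column(design,
      sample_id = paste0("S", seq_len(nrow(design))), .before = 1)
  }
  if (nrow(design) == 0L) {
    return(list(spectra = spectra_set(grid, matrix(0, 0, length(grid)), character(0)),
                concentrations = design))
  }
  clean <- mix_beer_lambert(components, design, grid)
  list(spectra = distort(clean, cfg), concentrations = design)
}

#' @rdname spectra_io
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_set"))
  wide <- tibble::as_tibble(t(spectra$absorbance), .name_repair = "minimal")
  names(wide) <- spectra$sample_ids
  wide <- tibble::add_column(wide, wavelength_nm = spectra$wavelengths, .before = 1)
  readr::write_csv(wide, path)
  invisible(path)
}

#' Read and write spectra as wide CSV
#'
#' Wide format: first column `wavelength_nm`, then one column per sample, UTF-8
#' with '.' decimal separator.
#'
#' @param spectra A [spectra_set].
#' @param path File path.
#' @return `read_spectra_csv` returns a [spectra_set]; the writer returns the
#'   path invisibly.
#' @name spectra_io
#' @export
read_spectra_csv <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  if (names(wide)[1] != "wavelength_nm") {
    stop_mixcal("expected first column `wavelength_nm` in ", path)
  }
  spectra_set(wide$wavelength_nm,
              t(as.matrix(wide[, -1, drop = FALSE])),
              names(wide)[-1])
}

#' @rdname concentration_io
#' @export
write_concentrations_csv <- function(concentrations, path) {
  readr::write_csv(tibble::as_tibble(concentrations), path)
  invisible(path)
}

#' Read and write concentration tables as CSV
#'
#' Columns: `sample_id`, optional `set`, then one numeric column per analyte
#' in ug/mL.
#'
#' @param concentrations Tibble of concentrations.
#' @param path File path.
#' @return `read_concentrations_csv` returns a tibble.
#' @name concentration_io
#' @export
read_concentrations_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
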