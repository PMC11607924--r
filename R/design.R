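# Multilevel multifactor calibration design: 5 coded levels {-2..+2}, 3
# factors, 25 runs built from a single cyclic generator, plus the packaged
# calibration/stability/test layout.

#' The canonical 24-run cyclic design generator
#'
#' Coded first-factor levels of calibration runs 2..25. Run 1 sits at the
#' centre (all factors coded 0); the column for factor f over runs 2..25 is
#' this sequence cyclically advanced by f-1 positions. The sequence is shipped
#' as a constant (it is the generator the packaged calibration layout uses)
#' and its balance and orthogonality are enforced by [generate_multilevel_design()].
#'
#' @return Integer vector of length 24 with values in -2..2.
#' @export
table1_generator <- function() {
  c(0L, -2L, -2L, 2L, -1L, 2L, 0L, -1L, -1L, 1L, 2L, 1L,
    0L, 2L, 2L, -2L, 1L, -2L, 0L, 1L, 1L, -1L, -2L, -1L)
}

#' Generate the 25-run five-level multifactor calibration design
#'
#' Builds the coded design matrix: run 1 at the all-zero centre point, then
#' for factor f the generator sequence advanced cyclically by f-1 positions
#' over runs 2..25. For a valid generator every level occurs exactly five
#' times per factor and distinct coded columns have zero dot product
#' (mutually orthogonal factors).
#'
#' @param generator Coded sequence of length `L^2 - 1` over the five-level
#'   alphabet -2..2; default [table1_generator()].
#' @param n_factors Number of factors (analytes), default 3.
#' @param factor_names Optional character names, default `PIO, ALG, GLM`.
#' @return Tibble with `sample_id` ("M1".."M25") and one `<factor>_code`
#'   integer column per factor.
#' @export
generate_multilevel_design <- function(generator = table1_generator(),
                                       n_factors = 3,
                                       factor_names = NULL) {
  generator <- as.integer(generator)
  if (length(generator) != 24L) {
    stop_mixcal("generator must have length 24 (runs 2..25)")
  }
  if (!all(generator %in% -2:2)) {
    stop_mixcal("generator entries must be coded levels in -2..2")
  }
  counts <- table(factor(generator, levels = -2:2))
  # run 1 contributes the fifth 0; the generator itself must carry 4 zeros
  # and 5 of every other level for the design to be balanced
  if (!(counts[["0"]] == 4L && all(counts[c("-2", "-1", "1", "2")] == 5L))) {
    stop_mixcal("generator is unbalanced: need five of each level per factor ",
                "(counting the centre run)")
  }
  factor_names <- factor_names %||% c("PIO", "ALG", "GLM")[seq_len(n_factors)]
  if (length(factor_names) != n_factors) {
    stop_mixcal("factor_names must have length n_factors")
  }
  coded <- matrix(0L, nrow = 25L, ncol = n_factors)
  for (f in seq_len(n_factors)) {
    shift <- f - 1L
    idx <- ((seq_len(24L) - 1L + shift) %% 24L) + 1L
    coded[2:25, f] <- generator[idx]
  }
  gram <- crossprod(coded)
  if (any(abs(gram[upper.tri(gram)]) > 0)) {
    stop_mixcal("generator does not yield orthogonal coded columns")
  }
  out <- tibble::as_tibble(as.data.frame(coded))
  names(out) <- paste0(factor_names, "_code")
  tibble::add_column(out, sample_id = paste0("M", 1:25), .before = 1)
}

#' Default coded-level to concentration mapping
#'
#' Centre and step per analyte (ug/mL): PIO 30 +/- 3, ALG 25 +/- 2.5,
#' GLM 4.0 +/- 0.4, spanning the calibration ranges 24-36, 20-30 and
#' 3.2-4.8 ug/mL over coded levels -2..+2.
#'
#' @return Named list of `c(center, step)` pairs.
#' @export
default_level_mapping <- function() {
  list(PIO = c(center = 30, step = 3),
       ALG = c(center = 25, step = 2.5),
       GLM = c(center = 4.0, step = 0.4))
}

#' Map a coded design to concentrations
#'
#' `concentration = center + step * code` per factor.
#'
#' @param coded Tibble from [generate_multilevel_design()] (`sample_id` +
#'   `<factor>_code` columns).
#' @param mapping Named list of `c(center, step)`; default
#'   [default_level_mapping()]. Steps must be > 0.
#' @param set Set label attached to every row, default `"M"`.
#' @return Tibble `sample_id`, `set`, one concentration column per factor.
#' @export
map_levels <- function(coded, mapping = default_level_mapping(), set = "M") {
  coded <- tibble::as_tibble(coded)
  code_cols <- grep("_code$", names(coded), value = TRUE)
  if (length(code_cols) == 0L) stop_mixcal("no `*_code` columns found")
  factors <- sub("_code$", "", code_cols)
  if (!all(factors %in% names(mapping))) {
    stop_mixcal("mapping must cover factors: ", paste(factors, collapse = ", "))
  }
  out <- tibble::tibble(
    sample_id = coded$sample_id %||% paste0("M", seq_len(nrow(coded))),
    set = set
  )
  for (f in factors) {
    code <- coded[[paste0(f, "_code")]]
    if (!all(code %in% -2:2)) {
      stop_mixcal("factor ", f, " has codes outside the -2..2 alphabet")
    }
    m <- mapping[[f]]
    if (m[["step"]] <= 0) stop_mixcal("mapping step for ", f, " must be > 0")
    out[[f]] <- m[["center"]] + m[["step"]] * code
  }
  out
}

#' Diagnostics for a concentration design
#'
#' Computes, on the mean-centred concentration matrix: per-factor means,
#' pairwise factor correlations, level-occupancy counts, and the first (up to)
#' three principal-component scores via singular value decomposition, for the
#' standard design scores plot. If `test` rows are supplied they are projected
#' onto the same components and flagged when they fall outside the calibration
#' bounding box.
#'
#' @param design Concentration tibble (`sample_id`, optional `set`, factor
#'   columns); at least 3 samples and 2 factors with non-zero variance.
#' @param test Optional tibble of test samples with the same factor columns.
#' @return Object of class `design_diagnostics`: list with `means`,
#'   `correlations`, `level_counts`, `scores` (tibble with `sample_id`, `set`,
#'   `PC1..`), `outside_hull` (logical per test row).
#' @export
design_diagnostics <- function(design, test = NULL) {
  design <- tibble::as_tibble(design)
  fac <- setdiff(names(design), c("sample_id", "set"))
  if (length(fac) < 2L) stop_mixcal("need at least 2 factors")
  X <- as.matrix(design[, fac, drop = FALSE])
  if (nrow(X) < 3L) stop_mixcal("need at least 3 samples")
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop_mixcal("zero-variance factor column; diagnostics are undefined")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  k <- min(3L, ncol(Xc), nrow(Xc) - 1L)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  score_tbl <- dplyr::bind_cols(
    tibble::tibble(sample_id = design$sample_id %||% as.character(seq_len(nrow(X))),
                   set = design$set %||% "M"),
    tibble::as_tibble(scores)
  )
  outside <- NULL
  if (!is.null(test)) {
    test <- tibble::as_tibble(test)
    Xt <- as.matrix(test[, fac, drop = FALSE])
    Tc <- sweep(Xt, 2, mu)
    t_scores <- Tc %*% sv$v[, seq_len(k), drop = FALSE]
    colnames(t_scores) <- paste0("PC", seq_len(k))
    score_tbl <- dplyr::bind_rows(
      score_tbl,
      dplyr::bind_cols(
        tibble::tibble(sample_id = test$sample_id %||% paste0("T", seq_len(nrow(Xt))),
                       set = test$set %||% "T"),
        tibble::as_tibble(t_scores)
      )
    )
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    outside <- apply(Xt, 1, function(r) any(r < lo - 1e-9 | r > hi + 1e-9))
  }
  lev <- lapply(fac, function(f) sort(table(X[, f]), decreasing = FALSE))
  names(lev) <- fac
  structure(
    list(means = stats::setNames(mu, fac),
         correlations = stats::cor(X),
         level_counts = lev,
         scores = score_tbl,
         outside_hull = outside),
    class = "design_diagnostics"
  )
}

#' @export
print.design_diagnostics <- function(x, ...) {
  cat("<design_diagnostics>\n  factor means:",
      paste(sprintf("%s=%.3g", names(x$means), x$means), collapse = ", "), "\n")
  off <- x$correlations[upper.tri(x$correlations)]
  cat(sprintf("  max |pairwise correlation|: %.3g\n", max(abs(off))))
  invisible(x)
}

# md5 of the packaged design table, frozen when the fixture was written
.TABLE1_MD5 <- "1463268351c054fb80beae6573a2c312"

#' Load the packaged calibration / stability / test concentration layout
#'
#' Returns the full 43-row layout used throughout the package: 25 calibration
#' rows (set `M`) from the five-level cyclic design, 6 replicate instrumental
#' stability rows (set `St`, all at PIO 27.00, ALG 22.50, GLM 4.40 ug/mL) and
#' 12 test rows (set `T`) inside the calibration ranges. The file is
#' checksum-verified on load.
#'
#' @return Tibble `sample_id`, `set`, `PIO`, `ALG`, `GLM` (ug/mL).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "design_table1.csv", package = "mixcal",
                      mustWork = TRUE)
  if (unname(tools::md5sum(path)) != .TABLE1_MD5) {
    stop_mixcal("packaged design fixture is corrupted (checksum mismatch)")
  }
  x <- readr::read_csv(path, show_col_types = FALSE)
  names(x) <- sub("_ugmL$", "", names(x))
  x
}

#' Write a concentration design as CSV
#'
#' Columns `sample_id, set, PIO_ugmL, ALG_ugmL, GLM_ugmL` (factor columns get
#' the `_ugmL` suffix).
#'
#' @param design Concentration tibble.
#' @param path Output path.
#' @export
write_design_csv <- function(design, path) {
  design <- tibble::as_tibble(design)
  fac <- setdiff(names(design), c("sample_id", "set"))
  names(design)[match(fac, names(design))] <- paste0(fac, "_ugmL")
  readr::write_csv(design, path)
  invisible(path)
}
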