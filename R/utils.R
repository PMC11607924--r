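# Internal helpers: argument checks and seeded sub-streams.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mixcal <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_mixcal(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_min && x <= min) stop_mixcal(sprintf("`%s` must be > %g", name, min))
  if (!strict_min && x < min) stop_mixcal(sprintf("`%s` must be >= %g", name, min))
  invisible(x)
}

# Evaluate `expr` under a deterministic RNG state derived from (seed, counter),
# restoring the caller's RNG state afterwards. Each (seed, counter) pair opens
# an independent reproducible sub-stream, so per-sample draws do not depend on
# how many draws earlier samples consumed.
with_substream <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  sub <- (as.double(seed) * 48271 + as.double(counter) * 16807) %% 2147483647
  set.seed(as.integer(sub))
  force(expr)
}

is_uniform_grid <- function(x, tol = 1e-9) {
  if (length(x) < 2L) return(TRUE)
  d <- diff(x)
  all(d > 0) && (max(d) - min(d)) < tol
}
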