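#' First threshold crossing of a sampled series
#'
#' Shared crossing rule used by both the colorimetric and the conductometric
#' endpoint: the index of the first sample whose value is greater than or
#' equal to `level`. No interpolation is performed, so the time resolution of
#' the returned index is the sampling grid of the input.
#'
#' @param values numeric vector of sampled values.
#' @param level threshold level on the same scale as `values`.
#' @return integer index of the first crossing, or `NA_integer_` if the level
#'   is never reached.
#' @export
first_crossing_index <- function(values, level) {
  stopifnot(is.numeric(values), length(values) >= 1L, is.finite(level))
  idx <- which(values >= level)
  if (length(idx) == 0L) NA_integer_ else idx[[1L]]
}

# round-half-up to integer; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

# deterministic child seed below 2^31, for fanning one user seed
# out to independent simulation repeats
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  code
}

stop_dissolvr <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dissolvr_error")))
}
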