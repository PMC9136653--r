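#' @keywords internal
"_PACKAGE"

# Condition helpers: every user-facing failure carries a subclass so the CLI
# can map it onto an exit code (validation vs data error).

abort_validation <- function(msg) {
  stop(structure(
    class = c("affectner_validation_error", "affectner_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_data <- function(msg) {
  stop(structure(
    class = c("affectner_data_error", "affectner_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Round half up
#'
#' Rounds to `digits` decimal places with ties going away from zero for
#' positive input (0.05 -> 0.1), matching the convention used when printing
#' percentages in clinical reports. Base R `round()` rounds half to even,
#' which would print 62.65 as 62.6.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic code in the package
# funnels through this so that library use never perturbs user RNG state.
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a per-unit substream seed from a master seed and an index, kept
# strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629
}

# 0-based, half-open character slice of a string (code points, not bytes).
slice_text <- function(text, start, end) {
  substring(text, start + 1, end)
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)
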