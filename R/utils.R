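# Internal helpers shared across modules.

#' Evaluate an expression under a local, restorable RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a `seed` argument fully determines their output
#' without clobbering the caller's RNG state.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# derive a stream-specific child seed; keeps results of independent stages
# decoupled while remaining a pure function of (seed, stream)
child_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream)) %% 2147483587L
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], not %s.",
                  name, deparse(x)))
  }
  invisible(x)
}

assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) &&
    (x > 0 || (!positive && x >= 0))
  if (!ok) {
    abort(sprintf("`%s` must be a single %s integer.",
                  name, if (positive) "positive" else "non-negative"))
  }
  invisible(as.integer(x))
}

# moving average with window 2k+1, edges averaged over the available span
moving_average <- function(x, k = 1L) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - k)
    hi <- min(n, i + k)
    mean(x[lo:hi])
  }, numeric(1))
}
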