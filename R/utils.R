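# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the global generator, evaluates `expr`, and restores whatever RNG
#' state existed before, so library code never perturbs a user's random
#' stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive `n` child seeds from a master seed, so that
# per-neuron / per-permutation streams are independent and reproducible.
# Seeds stay below 2^31 (R integers are 32-bit).
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Scalar-argument validators -------------------------------------------------

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}

check_prob <- function(x, name) {
  check_scalar(x, name)
  if (x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Sorted-spike-train sanity check; spike times are seconds.
check_train <- function(x, name = "train") {
  if (length(x) == 0L) return(invisible(numeric(0)))
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be a numeric spike-time vector without NA", name),
         call. = FALSE)
  }
  if (is.unsorted(x)) x <- sort(x)
  invisible(x)
}
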