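# Internal helpers shared across modules.

#' Evaluate code under a local RNG state
#'
#' Runs `expr` with the random number generator seeded to `seed`, restoring
#' the caller's RNG state afterwards so library code never perturbs the
#' global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

# Derive a deterministic sub-seed from a base seed and a stream label, kept
# within the 32-bit integer range. Each simulator draws from its own stream
# so that, e.g., adding genes to the bulk simulator cannot shift the peak
# coordinates of the accessibility simulator.
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}

# Scalar validators --------------------------------------------------------

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("'%s' must be a single number in (0, 1)", name))
  }
  invisible(as.numeric(x))
}

assert_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("'%s' must be a single number >= %s", name, format(min)))
  }
  invisible(as.numeric(x))
}
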