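# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package functions never perturb the user's random stream.
#'
#' @param seed Integer seed, or `NULL` to run with the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# Derive a stream of child seeds from one master seed; keeps stages of the
# pipeline independently reseedable while staying within 32-bit range.
derive_seeds <- function(seed, n, salt = 0L) {
  with_seed(as.integer(seed) %% 2147483647L + salt,
            sample.int(2147483646L, n))
}

stop_arg <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_arg(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lo &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) stop_arg(sprintf("'%s' must be in [%g, %g%s", name, lo, hi,
                            if (open_hi) ")" else "]"))
  as.numeric(x)
}

# Geometric mean of strictly positive values.
geomean <- function(x) exp(mean(log(x)))

genotype_levels <- function() c("XX", "XO", "XY")
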