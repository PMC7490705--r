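#' Round to nearest integer, halves away from zero
#'
#' Commercial ("half away from zero") rounding, as used for the printed
#' percentage columns: 17.815 -> 18, 90.85 -> 91, 46.875 -> 47. Base
#' `round()` rounds half to even and would disagree on exact halves.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 46.875, 17.815))
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Express a count ratio as an integer percentage
#'
#' @param numerator,denominator Nonnegative counts; `denominator` must be
#'   positive.
#' @return Integer percent, rounded half away from zero.
#' @export
#' @examples
#' percent_of(331, 1858) # container coverage, Season 1
percent_of <- function(numerator, denominator) {
  stopifnot(denominator > 0)
  as.integer(round_half_up(100 * numerator / denominator))
}

# Derive a reproducible 31-bit substream seed from a master seed and a
# character key. Multiplicative hashing keeps independent cells (sweep
# grid points, replicates) on distinct, order-independent streams.
derive_seed <- function(master_seed, key) {
  h <- 0
  for (b in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer((h + as.numeric(master_seed) %% 2147483647) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream. A NULL seed leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Validation helpers ---------------------------------------------------------

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a proportion in [0, 1].", name), call. = FALSE)
  }
  invisible(x)
}

assert_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && !anyNA(x) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) {
    stop(sprintf(
      "`%s` must be %s.", name,
      if (strict) "positive" else "nonnegative"
    ), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, strict = FALSE) {
  ok <- is.numeric(x) && !anyNA(x) && all(x == floor(x)) &&
    if (strict) all(x > 0) else all(x >= 0)
  if (!ok) {
    stop(sprintf(
      "`%s` must contain %s integers.", name,
      if (strict) "positive" else "nonnegative"
    ), call. = FALSE)
  }
  invisible(x)
}
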