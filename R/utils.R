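#' @import methods
NULL

# Amino-acid alphabet used throughout; ambiguity codes (B, Z, X, *) are
# deliberately excluded because consensus-motif semantics are undefined
# for them.
AA_ALPHABET_20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded at `seed`,
#' then restores the caller's RNG state, so seeded generators leave no
#' global side effects.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(low, high)` of proportions.
#' @examples
#' clopperPearson(10, 23)
#' @export
clopperPearson <- function(x, n, conf = 0.95) {
  stopifnot(length(n) %in% c(1L, length(x)), all(n >= 1), all(x >= 0),
            all(x <= n))
  if (length(n) == 1L) n <- rep(n, length(x))
  alpha <- 1 - conf
  low <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  high <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  if (length(x) == 1L) c(low = low, high = high) else cbind(low = low, high = high)
}

# Round half away from zero: matches how printed percentages like 43% and
# 3% are obtained from 10/23 and 1/30.
roundHalfAway <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Display a proportion as a whole-number percentage
#'
#' Rounds half away from zero, so 0.4348 prints as 43 and 0.0333 as 3.
#'
#' @param p proportion(s) in \[0, 1\].
#' @return numeric percentage(s).
#' @export
percentDisplay <- function(p) {
  roundHalfAway(100 * p)
}

# Two-sided exact binomial p-value by doubling the smaller tail, capped
# at 1. Used for spore-count tests where the printed counts are tiny.
binomTwoSidedDoubled <- function(x, n, p0) {
  lower <- stats::pbinom(x, n, p0)
  upper <- stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

# Validate that counts are non-negative integers.
checkCounts <- function(x, what = "count") {
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop(what, " must be non-negative integers", call. = FALSE)
  }
  invisible(TRUE)
}
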