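#' Build a spore genotype-class table
#'
#' Viable-colony counts by marker phenotype from a tetrad dissection or
#' random spore analysis of a `DNA2/dna2::URA3` x `PIF1-variant/pif1::KANMX`
#' diploid. Ura+ marks `dna2` deletion spores; G418 resistance marks
#' `pif1::KANMX` spores, so Ura+ G418-sensitive colonies are the
#' `dna2` deletion spores rescued by the PIF1 variant alone.
#'
#' @param ura_plus_g418s,ura_plus_g418r,ura_minus_g418s,ura_minus_g418r
#'   viable-colony counts.
#' @param source `"tetrad"` or `"rsa"`.
#' @param n_tetrads number of dissected tetrads (tetrad source only).
#' @return a validated list of class `"sporeTable"`.
#' @export
sporeTable <- function(ura_plus_g418s, ura_plus_g418r,
                       ura_minus_g418s, ura_minus_g418r,
                       source = c("tetrad", "rsa"), n_tetrads = NA_integer_) {
  source <- match.arg(source)
  counts <- c(ura_plus_g418s = ura_plus_g418s, ura_plus_g418r = ura_plus_g418r,
              ura_minus_g418s = ura_minus_g418s, ura_minus_g418r = ura_minus_g418r)
  checkCounts(counts)
  if (source == "tetrad") {
    if (is.na(n_tetrads)) stop("tetrad tables need n_tetrads", call. = FALSE)
    if (sum(counts) > 4L * n_tetrads) {
      stop("viable spores exceed 4 x n_tetrads", call. = FALSE)
    }
  }
  structure(list(counts = as.integer(counts) |> stats::setNames(names(counts)),
                 source = source, n_tetrads = as.integer(n_tetrads)),
            class = "sporeTable")
}

#' @export
print.sporeTable <- function(x, ...) {
  cat(sprintf("sporeTable (%s%s)\n", x$source,
              if (!is.na(x$n_tetrads)) sprintf(", %d tetrads", x$n_tetrads) else ""))
  print(x$counts)
  invisible(x)
}

#' Suppression fraction among Ura+ (dna2-deleted) spores
#'
#' Fraction of Ura+ viable colonies that are G418-sensitive, i.e. the
#' `dna2` deletion spores kept alive by the PIF1 variant rather than by
#' `pif1::KANMX`. Exact Clopper-Pearson 95% CI.
#'
#' @param table a [sporeTable()], or the G418-sensitive count.
#' @param n_g418r G418-resistant count when `table` is a bare count.
#' @param conf confidence level.
#' @return list with `fraction`, `ci_low`, `ci_high`, `n_s`, `n_total`.
#' @examples
#' suppressionFraction(8, 34)  # random-spore counts: 8/42
#' @export
suppressionFraction <- function(table, n_g418r = NULL, conf = 0.95) {
  if (inherits(table, "sporeTable")) {
    s <- table$counts[["ura_plus_g418s"]]
    r <- table$counts[["ura_plus_g418r"]]
  } else {
    s <- table
    r <- n_g418r
  }
  checkCounts(c(s, r))
  n <- s + r
  if (n < 1) stop("need >= 1 Ura+ colony", call. = FALSE)
  ci <- clopperPearson(s, n, conf)
  list(fraction = s / n, ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
       n_s = s, n_total = n)
}

#' Mendelian control test on Ura- spores
#'
#' Among Ura- (DNA2 wild-type) colonies both PIF1 classes are fully
#' viable, so G418-sensitive and -resistant counts should be 1:1. Exact
#' two-sided binomial test against 0.5 (doubled smaller tail, capped
#' at 1); the p-value is invariant to swapping the marker labels.
#'
#' @param table a [sporeTable()], or the G418-sensitive count.
#' @param n_g418r G418-resistant count when `table` is a bare count.
#' @return list with `p.value`, `n_s`, `n_total`.
#' @export
testMendelianControl <- function(table, n_g418r = NULL) {
  if (inherits(table, "sporeTable")) {
    s <- table$counts[["ura_minus_g418s"]]
    r <- table$counts[["ura_minus_g418r"]]
  } else {
    s <- table
    r <- n_g418r
  }
  checkCounts(c(s, r))
  n <- s + r
  if (n < 1) stop("need >= 1 Ura- colony", call. = FALSE)
  list(p.value = binomTwoSidedDoubled(s, n, 0.5), n_s = s, n_total = n)
}

#' Test the observed suppression against a null fraction
#'
#' Exact binomial test of the Ura+ G418-sensitive count against
#' `null_fraction`. The two natural nulls: 0 (no suppression — the
#' `dna2` deletion PIF1-variant class is dead, as in the wild-type PIF1
#' cross) and 0.5 (full suppression — parity with the `dna2 pif1` double
#' deletion class). Two-sided p by doubling the smaller tail, capped at
#' 1. A degenerate null of exactly 0 with any G418-sensitive spores
#' observed is reported as p = 0 with a flag.
#'
#' @param table a [sporeTable()], or the G418-sensitive count.
#' @param null_fraction null value in \[0, 1).
#' @param n_g418r G418-resistant count when `table` is a bare count.
#' @return list with `p.value`, `null_fraction`, `flags`.
#' @export
testSuppression <- function(table, null_fraction = 0.5, n_g418r = NULL) {
  if (inherits(table, "sporeTable")) {
    s <- table$counts[["ura_plus_g418s"]]
    r <- table$counts[["ura_plus_g418r"]]
  } else {
    s <- table
    r <- n_g418r
  }
  checkCounts(c(s, r))
  n <- s + r
  if (n < 1) stop("need >= 1 Ura+ colony", call. = FALSE)
  if (null_fraction < 0 || null_fraction >= 1) {
    stop("null_fraction must lie in [0, 1)", call. = FALSE)
  }
  flags <- character()
  if (null_fraction == 0) {
    # P(X >= s | p0 = 0) is 1 for s = 0 and 0 otherwise
    p <- if (s == 0) 1 else 0
    flags <- "null_degenerate"
  } else {
    p <- binomTwoSidedDoubled(s, n, null_fraction)
  }
  list(p.value = p, null_fraction = null_fraction, n_s = s, n_total = n,
       flags = flags)
}
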