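#' Classify a colony phenotype into a repair class
#'
#' Deterministic mapping of the two marker phenotypes scored in the
#' disomic chromosome III assay: adenine prototrophy/colony colour and
#' leucine prototrophy. Ade+ Leu- colonies form a pool (completed BIR,
#' GCR, or HC-II) that is resolved later by [decomposeOutcomes()];
#' Ade+ Leu+ is gene conversion (GC); Ade-red Leu- is chromosome loss
#' (CL); Ade-white Leu- is half-crossover class I (HC-I); any Ade- Leu+
#' combination is OTHER.
#'
#' @param ade one of `"plus"`, `"minus_red"`, `"minus_white"` (vectorized).
#' @param leu one of `"plus"`, `"minus"` (vectorized).
#' @return character vector over
#'   `ADE_PLUS_LEU_MINUS`, `GC`, `CL`, `HC_I`, `OTHER`.
#' @examples
#' classifyColony("minus_red", "minus")   # chromosome loss
#' classifyColony("minus_white", "minus") # half-crossover (HC-I)
#' @export
classifyColony <- function(ade, leu) {
  okAde <- c("plus", "minus_red", "minus_white")
  okLeu <- c("plus", "minus")
  if (any(!ade %in% okAde)) {
    stop("unknown ade phenotype: ", paste(setdiff(ade, okAde), collapse = ", "),
         call. = FALSE)
  }
  if (any(!leu %in% okLeu)) {
    stop("unknown leu phenotype: ", paste(setdiff(leu, okLeu), collapse = ", "),
         call. = FALSE)
  }
  out <- character(length(ade))
  out[ade == "plus" & leu == "minus"] <- "ADE_PLUS_LEU_MINUS"
  out[ade == "plus" & leu == "plus"] <- "GC"
  out[ade == "minus_red" & leu == "minus"] <- "CL"
  out[ade == "minus_white" & leu == "minus"] <- "HC_I"
  out[ade != "plus" & leu == "plus"] <- "OTHER"
  out
}

#' Tally a classified colony table into PhenotypeCounts
#'
#' @param tab data.frame with columns `strain`, `ade_phenotype`,
#'   `leu_phenotype`, `count` (the colony TSV schema).
#' @param strain optional strain to select; defaults to the only strain
#'   present.
#' @return a [PhenotypeCounts-class] object.
#' @export
tallyColonies <- function(tab, strain = NULL) {
  stopifnot(all(c("strain", "ade_phenotype", "leu_phenotype", "count") %in% names(tab)))
  if (is.null(strain)) {
    strain <- unique(tab$strain)
    if (length(strain) != 1L) stop("multiple strains present; pass strain=", call. = FALSE)
  }
  tab <- tab[tab$strain == strain, , drop = FALSE]
  cls <- classifyColony(tab$ade_phenotype, tab$leu_phenotype)
  tot <- function(k) sum(tab$count[cls == k])
  PhenotypeCounts(
    ade_plus_leu_minus = tot("ADE_PLUS_LEU_MINUS"), gc = tot("GC"),
    cl = tot("CL"), hc_i = tot("HC_I"), other = tot("OTHER"), label = strain
  )
}

#' Estimate the GCR fraction among Ade+ Leu- outcomes
#'
#' Binomial point estimate with an exact Clopper-Pearson 95% CI, from the
#' number of CHEF-karyotyped colonies showing a rearranged chromosome.
#'
#' @param n_rearranged colonies with an abnormal CHEF band.
#' @param n_tested colonies karyotyped.
#' @param conf confidence level (default 0.95).
#' @return a [GcrEstimate-class] object.
#' @examples
#' estimateGcrFraction(10, 23)  # prints as 43%
#' estimateGcrFraction(1, 30)   # prints as 3%
#' @export
estimateGcrFraction <- function(n_rearranged, n_tested, conf = 0.95) {
  checkCounts(c(n_rearranged, n_tested))
  if (n_tested < 1) stop("n_tested must be >= 1", call. = FALSE)
  if (n_rearranged > n_tested) stop("need n_rearranged <= n_tested", call. = FALSE)
  ci <- clopperPearson(n_rearranged, n_tested, conf)
  new("GcrEstimate", n_rearranged = as.integer(n_rearranged),
      n_tested = as.integer(n_tested),
      fraction = n_rearranged / n_tested,
      ci_low = unname(ci["low"]), ci_high = unname(ci["high"]))
}

#' Decompose Ade+ Leu- outcomes into BIR, GCR and HC-II
#'
#' Applies the sampled GCR fraction to the full Ade+ Leu- count, imputes
#' the invisible half-crossover class as HC-II = HC-I (random chromatid
#' segregation sends half of HC products into the Ade+ Leu- pool, see
#' [enumerateHcSegregation()]), and assigns the remainder to completed
#' BIR. The GCR count is kept real-valued; use [percentDisplay()] for
#' printing. If the corrections exceed the pool, BIR is floored at 0 and
#' the result flagged `"bir_floored"`.
#'
#' @param counts a [PhenotypeCounts-class] object.
#' @param gcr a [GcrEstimate-class] object (or a bare fraction in \[0,1\]).
#' @return an [OutcomeDecomposition-class] object. Frequencies are
#'   relative to all scored colonies (including `other`).
#' @examples
#' decomposeOutcomes(
#'   PhenotypeCounts(100, gc = 5, cl = 20, hc_i = 10),
#'   gcr = 0.30
#' )
#' @export
decomposeOutcomes <- function(counts, gcr) {
  stopifnot(is(counts, "PhenotypeCounts"))
  frac <- if (is(gcr, "GcrEstimate")) gcr@fraction else as.numeric(gcr)
  if (frac < 0 || frac > 1) stop("gcr fraction must lie in [0,1]", call. = FALSE)
  cnt <- counts@counts
  pool <- cnt[["ade_plus_leu_minus"]]
  gcrCount <- frac * pool
  hc2 <- cnt[["hc_i"]]
  bir <- pool - gcrCount - hc2
  flags <- character()
  if (bir < 0) {
    flags <- "bir_floored"
    bir <- 0
  }
  out <- c(gc = cnt[["gc"]], cl = cnt[["cl"]], hc_i = cnt[["hc_i"]],
           hc_ii = hc2, gcr = gcrCount, bir = bir, other = cnt[["other"]])
  denom <- sum(cnt)
  freq <- if (denom > 0) out / denom else out * 0
  new("OutcomeDecomposition", counts = out, frequencies = freq,
      denominator = denom, flags = flags, label = counts@label)
}

#' Contingency test between repair-outcome distributions
#'
#' Compares two phenotype-class distributions. k x 2 tables (k > 2
#' classes) use the chi-square test of homogeneity; 2 x 2 tables use
#' Fisher's exact test (two-sided). Classes with zero counts in both
#' conditions are dropped before testing.
#'
#' @param a,b [PhenotypeCounts-class] objects, or equal-length named
#'   count vectors, or for the 2 x 2 case length-2 vectors
#'   (successes, failures).
#' @return list with `statistic` (NA for Fisher), `p.value`, `method`,
#'   and the `table` tested.
#' @examples
#' compareDistributions(c(10, 13), c(1, 29))  # Fisher exact
#' @export
compareDistributions <- function(a, b) {
  toVec <- function(x) if (is(x, "PhenotypeCounts")) x@counts else x
  a <- toVec(a)
  b <- toVec(b)
  if (length(a) != length(b)) stop("class sets must match", call. = FALSE)
  checkCounts(c(a, b))
  if (sum(a) < 1 || sum(b) < 1) stop("each condition needs >= 1 colony", call. = FALSE)
  tab <- cbind(a = a, b = b)
  keep <- rowSums(tab) > 0
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) < 2L) stop("fewer than two non-empty classes", call. = FALSE)
  if (nrow(tab) == 2L) {
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    list(statistic = NA_real_, p.value = ft$p.value,
         method = "Fisher exact (two-sided)", table = tab)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab))
    list(statistic = unname(ct$statistic), p.value = ct$p.value,
         method = "chi-square homogeneity", table = tab)
  }
}
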