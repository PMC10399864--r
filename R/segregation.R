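#' Enumerate half-crossover chromatid segregation at mitosis
#'
#' A half-crossover (HC) fuses part of the broken recipient chromosome III
#' to part of the donor, destroying the donor's ADE3 side while keeping
#' the ADE1-proximal fragment. At the following mitosis the HC chromosome
#' segregates with one of the two remaining intact chromatids: with an
#' intact full-length donor chromatid the daughter is Ade+ Leu- (HC-II,
#' genetically indistinguishable from completed BIR); with the truncated
#' recipient chromatid (or none) it is Ade-white Leu- (HC-I). Under
#' random segregation the two scenarios are equiprobable, so exactly half
#' of scored HC products fall in each class — the premise of the
#' HC-II = HC-I imputation in [decomposeOutcomes()].
#'
#' @param hc_type_ii_weight probability that the HC chromosome
#'   co-segregates with an intact donor chromatid (default 0.5).
#' @return list with `fraction_hc_ii` (equal to the weight; exactly 1/2
#'   at the default) and `scenarios`, a data.frame mapping each daughter
#'   genotype to its phenotype class and probability.
#' @examples
#' enumerateHcSegregation()$fraction_hc_ii  # exactly 0.5
#' @export
enumerateHcSegregation <- function(hc_type_ii_weight = 0.5) {
  w <- hc_type_ii_weight
  if (length(w) != 1L || !is.finite(w) || w < 0 || w > 1) {
    stop("hc_type_ii_weight must lie in [0,1]", call. = FALSE)
  }
  scenarios <- data.frame(
    scenario = c("HC with intact donor chromatid",
                 "HC with truncated recipient chromatid"),
    daughter_genotype = c("HC fusion + full-length donor",
                          "HC fusion + truncated recipient"),
    phenotype = c("Ade+ Leu-", "Ade-white Leu-"),
    class = c("HC_II", "HC_I"),
    probability = c(w, 1 - w),
    stringsAsFactors = FALSE
  )
  list(fraction_hc_ii = w, scenarios = scenarios)
}

#' Simulate colony outcomes from the segregation model
#'
#' Each colony independently draws a repair mechanism from the
#' categorical distribution in `params`; marker phenotypes follow the
#' assay logic: BIR and GCR score Ade+ Leu-; GC scores Ade+ Leu+; CL
#' scores Ade-red Leu-; an HC product is a coin flip with
#' `hc_type_ii_weight`: HC-II joins the Ade+ Leu- pool, HC-I scores
#' Ade-white Leu-. The same seed and parameters always give identical
#' output; the caller's RNG state is untouched.
#'
#' @param params a [SegregationParams-class] object (carries the seed).
#' @param n number of colonies (>= 1).
#' @return list with `counts`, a [PhenotypeCounts-class]; and `truth`,
#'   a data.frame of per-colony mechanism labels and, for HC colonies,
#'   the segregation class drawn.
#' @export
simulateColonies <- function(params, n) {
  stopifnot(is(params, "SegregationParams"))
  validObject(params)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  withSeed(params@seed, {
    mech <- sample(MECHANISMS, n, replace = TRUE, prob = params@p)
    hcClass <- rep(NA_character_, n)
    isHc <- mech == "hc"
    if (any(isHc)) {
      hcClass[isHc] <- ifelse(
        stats::runif(sum(isHc)) < params@hc_type_ii_weight, "HC_II", "HC_I"
      )
    }
    pool <- sum(mech %in% c("bir", "gcr")) + sum(hcClass == "HC_II", na.rm = TRUE)
    counts <- PhenotypeCounts(
      ade_plus_leu_minus = pool,
      gc = sum(mech == "gc"),
      cl = sum(mech == "cl"),
      hc_i = sum(hcClass == "HC_I", na.rm = TRUE),
      other = sum(mech == "other"),
      label = sprintf("simulated(seed=%d)", params@seed)
    )
    list(counts = counts,
         truth = data.frame(colony = seq_len(n), mechanism = mech,
                            hc_class = hcClass, stringsAsFactors = FALSE))
  })
}

#' Expected phenotype-class probabilities under the segregation model
#'
#' Analytic counterpart of [simulateColonies()]: the probability of each
#' scored phenotype class given the mechanism probabilities and the HC
#' segregation weight.
#'
#' @param params a [SegregationParams-class] object.
#' @return named numeric vector over the five phenotype classes.
#' @export
expectedPhenotypeProbs <- function(params) {
  stopifnot(is(params, "SegregationParams"))
  p <- params@p
  w <- params@hc_type_ii_weight
  c(ade_plus_leu_minus = unname(p["bir"] + p["gcr"] + p["hc"] * w),
    gc = unname(p["gc"]),
    cl = unname(p["cl"]),
    hc_i = unname(p["hc"] * (1 - w)),
    other = unname(p["other"]))
}
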