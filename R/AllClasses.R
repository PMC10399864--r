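#' ProteinSequence: a 1-based anchored amino-acid sequence
#'
#' Holds a protein (sub)sequence together with the full-protein coordinate
#' of its first residue, so that motif positions can be reported in the
#' residue numbering of the intact protein (e.g. the 859-aa Pif1). The
#' full-protein coordinate of residue \eqn{i} is \code{anchor + i - 1}.
#'
#' @slot id character label.
#' @slot residues upper-case string over the 20 amino-acid alphabet
#'   (may be empty only when explicitly constructed empty).
#' @slot anchor 1-based full-protein coordinate of the first residue.
#' @export
setClass("ProteinSequence",
  representation(id = "character", residues = "character", anchor = "integer"),
  prototype(id = NA_character_, residues = "", anchor = 1L)
)

setValidity("ProteinSequence", function(object) {
  if (length(object@residues) != 1L) return("residues must be a single string")
  if (length(object@anchor) != 1L || is.na(object@anchor) || object@anchor < 1L) {
    return("anchor must be a single integer >= 1")
  }
  if (nchar(object@residues) > 0L) {
    chars <- strsplit(object@residues, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% AA_ALPHABET_20)
    if (length(bad)) {
      return(sprintf(
        "invalid residue '%s' at position %d (full-protein coordinate %d)",
        chars[bad[1L]], bad[1L], object@anchor + bad[1L] - 1L
      ))
    }
  }
  TRUE
})

#' Construct a ProteinSequence
#'
#' Lower-case residues are upper-cased with a warning; ambiguity codes
#' (B, Z, X, *) are rejected because motif matching is undefined for them.
#'
#' @param residues amino-acid string.
#' @param id optional label.
#' @param anchor 1-based full-protein coordinate of the first residue.
#' @return a [ProteinSequence-class] object.
#' @examples
#' ProteinSequence("DEQVKKRKLDY", id = "Pif1-candidate", anchor = 777)
#' @export
ProteinSequence <- function(residues, id = NA_character_, anchor = 1L) {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (grepl("[a-z]", residues)) {
    warning("lower-case residues upper-cased", call. = FALSE)
    residues <- toupper(residues)
  }
  new("ProteinSequence", id = as.character(id), residues = residues,
      anchor = as.integer(anchor))
}

setMethod("show", "ProteinSequence", function(object) {
  cat(sprintf(
    "ProteinSequence '%s': %d aa, anchored at residue %d\n",
    object@id, nchar(object@residues), object@anchor
  ))
  res <- object@residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(" ", res, "\n")
})

#' @rdname ProteinSequence
#' @param x a ProteinSequence.
#' @export
residues <- function(x) x@residues

#' @rdname ProteinSequence
#' @export
anchor <- function(x) x@anchor

#' PhenotypeCounts: colony marker-class counts for one strain
#'
#' Counts of the five scored phenotype classes in the disomic
#' chromosome III double-strand-break repair assay: Ade+ Leu- (the pool
#' containing completed BIR, GCR and HC-II), Ade+ Leu+ (gene conversion),
#' Ade-red Leu- (chromosome loss), Ade-white Leu- (half-crossover class I),
#' and anything else.
#'
#' @slot counts named integer vector with elements
#'   `ade_plus_leu_minus`, `gc`, `cl`, `hc_i`, `other`.
#' @slot label strain or condition label.
#' @export
setClass("PhenotypeCounts",
  representation(counts = "integer", label = "character")
)

PHENOTYPE_CLASSES <- c("ade_plus_leu_minus", "gc", "cl", "hc_i", "other")

setValidity("PhenotypeCounts", function(object) {
  if (!identical(names(object@counts), PHENOTYPE_CLASSES)) {
    return(paste("counts must be named:", paste(PHENOTYPE_CLASSES, collapse = ", ")))
  }
  if (any(is.na(object@counts)) || any(object@counts < 0L)) {
    return("all counts must be non-negative integers")
  }
  TRUE
})

#' Construct PhenotypeCounts
#'
#' @param ade_plus_leu_minus,gc,cl,hc_i,other class counts.
#' @param label strain/condition label.
#' @return a [PhenotypeCounts-class] object.
#' @examples
#' PhenotypeCounts(100, gc = 5, cl = 20, hc_i = 10, label = "WT")
#' @export
PhenotypeCounts <- function(ade_plus_leu_minus = 0, gc = 0, cl = 0,
                            hc_i = 0, other = 0, label = "") {
  cnt <- c(ade_plus_leu_minus = ade_plus_leu_minus, gc = gc, cl = cl,
           hc_i = hc_i, other = other)
  checkCounts(cnt)
  new("PhenotypeCounts", counts = structure(as.integer(cnt), names = PHENOTYPE_CLASSES),
      label = as.character(label))
}

#' @rdname PhenotypeCounts
#' @param x a PhenotypeCounts object.
#' @export
phenotypeCounts <- function(x) x@counts

#' @rdname PhenotypeCounts
#' @export
totalColonies <- function(x) sum(x@counts)

setMethod("show", "PhenotypeCounts", function(object) {
  cat(sprintf("PhenotypeCounts [%s], %d colonies\n", object@label,
              sum(object@counts)))
  print(object@counts)
})

#' GcrEstimate: fraction of rearranged Ade+ Leu- outcomes
#'
#' Binomial estimate (with exact Clopper-Pearson 95% CI) of the fraction
#' of gross chromosomal rearrangements among Ade+ Leu- colonies, as
#' scored by CHEF gel karyotyping of a sample of colonies.
#'
#' @slot n_rearranged,n_tested integer counts.
#' @slot fraction,ci_low,ci_high proportions.
#' @export
setClass("GcrEstimate",
  representation(n_rearranged = "integer", n_tested = "integer",
                 fraction = "numeric", ci_low = "numeric", ci_high = "numeric")
)

setValidity("GcrEstimate", function(object) {
  with_slots <- c(object@ci_low, object@fraction, object@ci_high)
  if (any(with_slots < 0) || any(with_slots > 1)) return("proportions must lie in [0,1]")
  if (object@ci_low > object@fraction || object@fraction > object@ci_high) {
    return("CI must bracket the fraction")
  }
  TRUE
})

setMethod("show", "GcrEstimate", function(object) {
  cat(sprintf(
    "GcrEstimate: %d/%d rearranged = %.4f (%.0f%%), 95%% CI [%.4f, %.4f]\n",
    object@n_rearranged, object@n_tested, object@fraction,
    percentDisplay(object@fraction), object@ci_low, object@ci_high
  ))
})

#' @rdname GcrEstimate-class
#' @param x a GcrEstimate.
#' @export
gcrFraction <- function(x) x@fraction

#' OutcomeDecomposition: repair classes after GCR correction and HC-II imputation
#'
#' @slot counts named numeric vector over
#'   `gc`, `cl`, `hc_i`, `hc_ii`, `gcr`, `bir`, `other`; GCR and BIR are
#'   real-valued because the GCR correction applies a fraction to a count.
#' @slot frequencies same names, relative to all scored colonies.
#' @slot denominator total colonies used for the frequencies.
#' @slot flags character vector of warnings (e.g. `"bir_floored"`).
#' @export
setClass("OutcomeDecomposition",
  representation(counts = "numeric", frequencies = "numeric",
                 denominator = "numeric", flags = "character",
                 label = "character")
)

DECOMPOSITION_CLASSES <- c("gc", "cl", "hc_i", "hc_ii", "gcr", "bir", "other")

setValidity("OutcomeDecomposition", function(object) {
  if (!identical(names(object@counts), DECOMPOSITION_CLASSES) ||
      !identical(names(object@frequencies), DECOMPOSITION_CLASSES)) {
    return(paste("counts/frequencies must be named:",
                 paste(DECOMPOSITION_CLASSES, collapse = ", ")))
  }
  if (any(object@frequencies < -1e-12) || any(object@frequencies > 1 + 1e-12)) {
    return("frequencies must lie in [0,1]")
  }
  if (!("bir_floored" %in% object@flags) &&
      abs(sum(object@frequencies) - 1) > 1e-9) {
    return("frequencies must sum to 1 within 1e-9 when no flooring occurred")
  }
  TRUE
})

setMethod("show", "OutcomeDecomposition", function(object) {
  cat(sprintf("OutcomeDecomposition [%s], %g colonies\n", object@label,
              object@denominator))
  out <- rbind(count = round(object@counts, 2),
               `freq (%)` = round(100 * object@frequencies, 1))
  print(out)
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @rdname OutcomeDecomposition-class
#' @param x an OutcomeDecomposition.
#' @export
decompositionCounts <- function(x) x@counts

#' @rdname OutcomeDecomposition-class
#' @export
decompositionFrequencies <- function(x) x@frequencies

#' SegregationParams: per-cell repair-mechanism probabilities
#'
#' Parameters of the colony-level generative model: each plated cell
#' repairs its broken chromatid by exactly one mechanism, and
#' half-crossover products segregate with the intact donor chromosome
#' (and thus score Ade+ Leu-, class HC-II) with probability
#' `hc_type_ii_weight`.
#'
#' @slot p named numeric vector `bir`, `gc`, `hc`, `cl`, `gcr`, `other`
#'   summing to 1.
#' @slot hc_type_ii_weight probability in \[0,1\] (default 0.5, the
#'   random-segregation value).
#' @slot seed integer seed for [simulateColonies()].
#' @export
setClass("SegregationParams",
  representation(p = "numeric", hc_type_ii_weight = "numeric", seed = "integer")
)

MECHANISMS <- c("bir", "gc", "hc", "cl", "gcr", "other")

setValidity("SegregationParams", function(object) {
  if (!identical(names(object@p), MECHANISMS)) {
    return(paste("p must be named:", paste(MECHANISMS, collapse = ", ")))
  }
  if (any(object@p < 0) || any(object@p > 1)) return("probabilities must lie in [0,1]")
  if (abs(sum(object@p) - 1) > 1e-12) return("probabilities must sum to 1 within 1e-12")
  w <- object@hc_type_ii_weight
  if (length(w) != 1L || w < 0 || w > 1) return("hc_type_ii_weight must lie in [0,1]")
  TRUE
})

#' @rdname SegregationParams-class
#' @param bir,gc,hc,cl,gcr,other mechanism probabilities (must sum to 1).
#' @param hc_type_ii_weight probability an HC product co-segregates with an
#'   intact donor.
#' @param seed integer RNG seed.
#' @return a [SegregationParams-class] object.
#' @examples
#' segregationParams(bir = 0.75, gc = 0.08, hc = 0.04, cl = 0.09,
#'                   gcr = 0.02, other = 0.02, seed = 1)
#' @export
segregationParams <- function(bir, gc, hc, cl, gcr, other,
                              hc_type_ii_weight = 0.5, seed = 1L) {
  new("SegregationParams",
      p = c(bir = bir, gc = gc, hc = hc, cl = cl, gcr = gcr, other = other),
      hc_type_ii_weight = hc_type_ii_weight, seed = as.integer(seed))
}

setMethod("show", "SegregationParams", function(object) {
  cat("SegregationParams (seed", object@seed, ")\n")
  print(object@p)
  cat("hc_type_ii_weight:", object@hc_type_ii_weight, "\n")
})

#' RateEstimate: background-corrected reversion rate
#'
#' Lys- to Lys+ reversion frequency per viable cell measured after DSB
#' induction, minus the pre-induction (0-hr) background, with a
#' percentile-bootstrap confidence interval over replicate cultures.
#'
#' @slot strain strain label.
#' @slot frequency_per_cell induced (7-hr) frequency.
#' @slot background_frequency pre-induction (0-hr) frequency.
#' @slot net_rate background-corrected rate (may be negative; flagged).
#' @slot ci_low,ci_high bootstrap CI bounds on the net rate.
#' @slot n_replicates replicates at the induced timepoint.
#' @slot freq_induced,freq_background per-replicate frequencies (kept for
#'   downstream paired bootstraps).
#' @slot flags character vector (e.g. `"negative_net_rate"`).
#' @export
setClass("RateEstimate",
  representation(strain = "character", frequency_per_cell = "numeric",
                 background_frequency = "numeric", net_rate = "numeric",
                 ci_low = "numeric", ci_high = "numeric",
                 n_replicates = "integer",
                 freq_induced = "numeric", freq_background = "numeric",
                 flags = "character")
)

setValidity("RateEstimate", function(object) {
  if (object@frequency_per_cell < 0 || object@background_frequency < 0) {
    return("frequencies must be >= 0")
  }
  if (!("negative_net_rate" %in% object@flags)) {
    if (object@ci_low > object@net_rate + 1e-15 ||
        object@net_rate > object@ci_high + 1e-15) {
      return("CI must bracket the net rate")
    }
  }
  TRUE
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf(
    "RateEstimate [%s]: net %.3g per cell (induced %.3g - background %.3g)\n",
    object@strain, object@net_rate, object@frequency_per_cell,
    object@background_frequency
  ))
  cat(sprintf("  95%% bootstrap CI [%.3g, %.3g], %d replicates\n",
              object@ci_low, object@ci_high, object@n_replicates))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @rdname RateEstimate-class
#' @param x a RateEstimate.
#' @export
netRate <- function(x) x@net_rate

#' DropletChannel: one ddPCR channel with Poisson-corrected concentration
#'
#' With templates Poisson-partitioned into droplets, the mean copies per
#' droplet is \eqn{\lambda = -\ln(1 - k/n)} where \eqn{k} of \eqn{n}
#' droplets are positive. The 95% CI is the exact binomial CI on the
#' positive fraction transformed through the same function.
#'
#' @slot locus locus label (e.g. "P2", "ACT1").
#' @slot n_total,n_positive droplet counts.
#' @slot lambda,lambda_ci_low,lambda_ci_high copies per droplet.
#' @export
setClass("DropletChannel",
  representation(locus = "character", n_total = "integer", n_positive = "integer",
                 lambda = "numeric", lambda_ci_low = "numeric",
                 lambda_ci_high = "numeric")
)

setValidity("DropletChannel", function(object) {
  if (object@n_positive < 0L || object@n_positive > object@n_total) {
    return("need 0 <= n_positive <= n_total")
  }
  if (object@lambda_ci_low > object@lambda + 1e-12 ||
      object@lambda > object@lambda_ci_high + 1e-12) {
    return("lambda CI must bracket lambda")
  }
  TRUE
})

setMethod("show", "DropletChannel", function(object) {
  cat(sprintf(
    "DropletChannel [%s]: %d/%d positive, lambda %.4f [%.4f, %.4f]\n",
    object@locus, object@n_positive, object@n_total, object@lambda,
    object@lambda_ci_low, object@lambda_ci_high
  ))
})

#' @rdname DropletChannel-class
#' @param x a DropletChannel.
#' @export
channelLambda <- function(x) x@lambda

#' KineticsFit: Boltzmann sigmoidal fit of a copy-number time course
#'
#' Least-squares fit of
#' \eqn{y(t) = base + (top - base) / (1 + \exp((t_{1/2} - t)/\tau))}.
#'
#' @slot base,top copy-number asymptotes.
#' @slot t_half hours at half-rise.
#' @slot tau slope parameter in hours (> 0 when converged).
#' @slot rss residual sum of squares.
#' @slot converged logical optimizer status.
#' @export
setClass("KineticsFit",
  representation(base = "numeric", top = "numeric", t_half = "numeric",
                 tau = "numeric", rss = "numeric", converged = "logical")
)

setMethod("show", "KineticsFit", function(object) {
  cat(sprintf(
    "KineticsFit: base %.3f, top %.3f, t_half %.2f h, tau %.3f h (rss %.3g, %s)\n",
    object@base, object@top, object@t_half, object@tau, object@rss,
    if (object@converged) "converged" else "NOT converged"
  ))
})
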