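#' ChIP-qPCR enrichment from quantification cycles
#'
#' Per replicate, the percent-of-input signal for a locus is
#' `dilution * eff^(cq_input - cq_ip)` (the input is plated diluted,
#' default 1:10; amplification efficiency fixed at 2 unless
#' calibrated). Enrichment is the target locus percent-input divided by
#' the control locus percent-input (ACT1 for MAT; YBL028C for CEN13 and
#' mtDNA), so the dilution factor and any global Cq shift cancel.
#'
#' @param replicates data.frame with columns `cq_ip_target`,
#'   `cq_input_target`, `cq_ip_control`, `cq_input_control` (one row per
#'   replicate), optionally `strain`, `locus`, `control_locus`.
#' @param input_dilution input dilution factor (default 10).
#' @param efficiency amplification efficiency per cycle (default 2).
#' @return list with `enrichment` (per replicate), `percent_input_target`,
#'   `percent_input_control`, `mean`, `sd`, `n`.
#' @examples
#' cq <- data.frame(cq_ip_target = 20, cq_input_target = 22,
#'                  cq_ip_control = 22, cq_input_control = 22)
#' chipEnrichment(cq)$enrichment  # 4: target IP is 2 cycles earlier
#' @export
chipEnrichment <- function(replicates, input_dilution = 10, efficiency = 2) {
  needed <- c("cq_ip_target", "cq_input_target", "cq_ip_control", "cq_input_control")
  missing <- setdiff(needed, names(replicates))
  if (length(missing)) {
    stop("missing Cq columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cq <- replicates[needed]
  if (any(!is.finite(as.matrix(cq))) || any(as.matrix(cq) <= 0)) {
    stop("Cq values must be finite and > 0", call. = FALSE)
  }
  if (input_dilution < 1) stop("input_dilution must be >= 1", call. = FALSE)
  piT <- input_dilution * efficiency^(cq$cq_input_target - cq$cq_ip_target)
  piC <- input_dilution * efficiency^(cq$cq_input_control - cq$cq_ip_control)
  enr <- piT / piC
  list(enrichment = enr, percent_input_target = piT,
       percent_input_control = piC,
       mean = mean(enr), sd = stats::sd(enr), n = length(enr))
}

#' Fold-reduction in enrichment between two strains with Welch t-test
#'
#' Ratio of mean enrichments (e.g. WT over mutant) and a two-sided
#' unpaired Welch t-test on the per-replicate enrichments.
#'
#' @param wt,mut outputs of [chipEnrichment()] (or numeric replicate
#'   vectors), >= 3 replicates each.
#' @return list with `ratio`, `statistic`, `df`, `p.value`, `method`.
#' @export
foldReduction <- function(wt, mut) {
  toVec <- function(x) if (is.list(x) && !is.null(x$enrichment)) x$enrichment else x
  wt <- toVec(wt)
  mut <- toVec(mut)
  if (length(wt) < 3L || length(mut) < 3L) {
    stop("need >= 3 replicates per strain", call. = FALSE)
  }
  tt <- stats::t.test(wt, mut, var.equal = FALSE)
  list(ratio = mean(wt) / mean(mut), statistic = unname(tt$statistic),
       df = unname(tt$parameter), p.value = tt$p.value,
       method = "Welch two-sample t-test")
}
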