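#' Build a plating experiment table
#'
#' One row per replicate culture plated on selective (Sc-Ade,Lys) and
#' permissive (Sc-Ade) media, with the dilution factor applied before
#' each plating.
#'
#' @param strain strain label.
#' @param timepoint_hr 0 (pre-induction background) or 7 (post-induction).
#' @param lys_colonies Lys+ colony counts on selective plates.
#' @param viable_colonies colony counts on permissive plates.
#' @param dilution_selective,dilution_permissive dilution factors (>= 1).
#' @return a validated data.frame in the plating TSV schema.
#' @export
platingExperiment <- function(strain, timepoint_hr, lys_colonies, viable_colonies,
                              dilution_selective = 1, dilution_permissive = 1) {
  n <- length(lys_colonies)
  if (n < 1L) stop("need >= 1 replicate", call. = FALSE)
  df <- data.frame(
    strain = strain, timepoint_hr = timepoint_hr, replicate = seq_len(n),
    lys_colonies = lys_colonies, viable_colonies = viable_colonies,
    dilution_selective = dilution_selective,
    dilution_permissive = dilution_permissive,
    stringsAsFactors = FALSE
  )
  validatePlating(df)
  df
}

validatePlating <- function(df) {
  checkCounts(df$lys_colonies, "lys_colonies")
  checkCounts(df$viable_colonies, "viable_colonies")
  if (any(df$dilution_selective < 1) || any(df$dilution_permissive < 1)) {
    stop("dilution factors must be >= 1", call. = FALSE)
  }
  if (!all(df$timepoint_hr %in% c(0, 7))) {
    stop("timepoint_hr must be 0 or 7", call. = FALSE)
  }
  invisible(df)
}

#' Per-cell reversion frequency of one replicate
#'
#' `frequency = (lys_colonies * dilution_selective) /
#' (viable_colonies * dilution_permissive)`: both counts are scaled back
#' to the undiluted culture, so the frequency is invariant to
#' proportional rescaling of the two dilutions.
#'
#' @param lys_colonies,viable_colonies plate counts (vectorized).
#' @param dilution_selective,dilution_permissive dilution factors.
#' @return numeric frequency per viable cell.
#' @examples
#' reversionFrequency(39, 100, 1, 1e5)  # 3.9e-06
#' @export
reversionFrequency <- function(lys_colonies, viable_colonies,
                               dilution_selective = 1, dilution_permissive = 1) {
  scaledViable <- viable_colonies * dilution_permissive
  if (any(scaledViable <= 0)) {
    stop("scaled viable count must be > 0", call. = FALSE)
  }
  (lys_colonies * dilution_selective) / scaledViable
}

platingFrequencies <- function(df) {
  reversionFrequency(df$lys_colonies, df$viable_colonies,
                     df$dilution_selective, df$dilution_permissive)
}

#' Estimate the background-corrected reversion rate
#'
#' Summarises per-replicate frequencies at the induced (7-hr) and
#' pre-induction (0-hr) timepoints and subtracts the background. The
#' default centre is the mean: in this assay mutations arise during the
#' fixed induction window rather than by clonal expansion, so replicate
#' counts are Poisson and the mean is the efficient, unbiased summary;
#' at mutant rates the expected count per culture is of order one and a
#' median collapses onto the integer grid. `center = "median"` is
#' available for jackpot-prone data. The CI is a seeded percentile
#' bootstrap over replicates (resampled independently per timepoint).
#' Negative net rates are reported and flagged, never clamped.
#'
#' @param exp_induced plating table at 7 hr (see [platingExperiment()]).
#' @param exp_background plating table at 0 hr; strains must match.
#' @param center `"mean"` (default) or `"median"`.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer bootstrap seed.
#' @param conf confidence level.
#' @return a [RateEstimate-class] object.
#' @export
estimateRate <- function(exp_induced, exp_background, center = c("mean", "median"),
                         n_boot = 2000, seed = 1L, conf = 0.95) {
  center <- match.arg(center)
  validatePlating(exp_induced)
  validatePlating(exp_background)
  strain <- unique(exp_induced$strain)
  if (length(strain) != 1L || !identical(strain, unique(exp_background$strain))) {
    stop("strains must match between timepoints", call. = FALSE)
  }
  if (!all(exp_induced$timepoint_hr == 7) || !all(exp_background$timepoint_hr == 0)) {
    stop("expected a 7-hr table and a 0-hr table", call. = FALSE)
  }
  f7 <- platingFrequencies(exp_induced)
  f0 <- platingFrequencies(exp_background)
  ctr <- if (center == "mean") mean else stats::median
  freq <- ctr(f7)
  bg <- ctr(f0)
  net <- freq - bg
  flags <- if (net < 0) "negative_net_rate" else character()

  boot <- withSeed(seed, {
    i7 <- matrix(sample.int(length(f7), n_boot * length(f7), replace = TRUE),
                 nrow = n_boot)
    i0 <- matrix(sample.int(length(f0), n_boot * length(f0), replace = TRUE),
                 nrow = n_boot)
    m7 <- matrix(f7[i7], nrow = n_boot)
    m0 <- matrix(f0[i0], nrow = n_boot)
    if (center == "mean") {
      rowMeans(m7) - rowMeans(m0)
    } else {
      apply(m7, 1L, stats::median) - apply(m0, 1L, stats::median)
    }
  })
  alpha <- 1 - conf
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 7))

  new("RateEstimate", strain = strain, frequency_per_cell = freq,
      background_frequency = bg, net_rate = net,
      ci_low = min(ci[1L], net), ci_high = max(ci[2L], net),
      n_replicates = length(f7), freq_induced = f7, freq_background = f0,
      flags = flags)
}

#' Fold-change between two rate estimates
#'
#' `ratio = netRate(a) / netRate(b)`, with a CI from a paired bootstrap:
#' each resample redraws replicates of both strains and recomputes the
#' ratio of net rates.
#'
#' @param a,b [RateEstimate-class] objects; `netRate(b)` must be > 0.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with `ratio`, `ci_low`, `ci_high`.
#' @export
foldChange <- function(a, b, n_boot = 2000, seed = 1L, conf = 0.95) {
  stopifnot(is(a, "RateEstimate"), is(b, "RateEstimate"))
  if (b@net_rate <= 0) stop("denominator net rate must be > 0", call. = FALSE)
  ratio <- a@net_rate / b@net_rate
  resampleNet <- function(f7, f0, n_boot) {
    m7 <- matrix(f7[sample.int(length(f7), n_boot * length(f7), replace = TRUE)],
                 nrow = n_boot)
    m0 <- matrix(f0[sample.int(length(f0), n_boot * length(f0), replace = TRUE)],
                 nrow = n_boot)
    rowMeans(m7) - rowMeans(m0)
  }
  boot <- withSeed(seed, {
    netA <- resampleNet(a@freq_induced, a@freq_background, n_boot)
    netB <- resampleNet(b@freq_induced, b@freq_background, n_boot)
    ok <- netB > 0
    (netA / netB)[ok]
  })
  alpha <- 1 - conf
  ci <- if (length(boot)) {
    unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  } else {
    c(NA_real_, NA_real_)
  }
  list(ratio = ratio, ci_low = ci[1L], ci_high = ci[2L])
}

#' Mann-Whitney comparison of replicate frequency sets
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test: exact for small,
#' tie-free samples, otherwise the normal approximation with tie
#' correction.
#'
#' @param a,b numeric vectors of per-replicate frequencies (>= 3 each).
#' @return list with `statistic` (U), `p.value`, `method`.
#' @export
compareRates <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L) {
    stop("need >= 3 replicates per group", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = wt$method)
}
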