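#' Generate a synthetic plating experiment (0-hr and 7-hr pair)
#'
#' Emulates the reversion-rate assay: per culture, Lys+ counts on the
#' selective plate are Poisson with mean
#' `rate * cells_per_culture / dilution_selective` (background rate only
#' at 0 hr; background + induced rate at 7 hr), and permissive-plate
#' viable counts are drawn around `cells_per_culture / dilution_permissive`
#' with a small Gaussian relative error (default 2%) from pipetting and
#' plating. Deterministic per seed.
#'
#' @param true_rate induced reversion rate per cell, in \[0, 1e-2\].
#' @param background_rate pre-induction rate per cell, in \[0, 1e-2\].
#' @param n_cultures replicate cultures (>= 1).
#' @param cells_per_culture cells plated per culture.
#' @param seed integer seed.
#' @param strain strain label.
#' @param dilution_selective,dilution_permissive plating dilutions.
#' @param viable_cv relative SD of the viable-count noise.
#' @return list with `t0` and `t7` plating tables (see
#'   [platingExperiment()]).
#' @export
generatePlating <- function(true_rate, background_rate = 0, n_cultures = 20,
                            cells_per_culture = 1e7, seed = 1L, strain = "synthetic",
                            dilution_selective = 1, dilution_permissive = 1e5,
                            viable_cv = 0.02) {
  if (true_rate < 0 || true_rate > 1e-2 || background_rate < 0 || background_rate > 1e-2) {
    stop("rates must lie in [0, 1e-2]", call. = FALSE)
  }
  if (n_cultures < 1) stop("n_cultures must be >= 1", call. = FALSE)
  withSeed(seed, {
    drawPlate <- function(rate, timepoint) {
      lys <- stats::rpois(n_cultures, rate * cells_per_culture / dilution_selective)
      viableMean <- cells_per_culture / dilution_permissive
      viable <- pmax(1L, as.integer(round(
        stats::rnorm(n_cultures, viableMean, viable_cv * viableMean)
      )))
      platingExperiment(strain, timepoint_hr = timepoint, lys_colonies = lys,
                        viable_colonies = viable,
                        dilution_selective = dilution_selective,
                        dilution_permissive = dilution_permissive)
    }
    list(t0 = drawPlate(background_rate, 0),
         t7 = drawPlate(background_rate + true_rate, 7))
  })
}

#' Generate synthetic ddPCR droplet counts
#'
#' Emulates Poisson partitioning of template into droplets: each droplet
#' is positive with probability `1 - exp(-lambda)`. Emits an induced
#' timepoint where the target concentration is `true_ratio * ref_lambda`
#' plus a matched 0-hr pair at ratio 1, each with its own reference
#' channel. Deterministic per seed.
#'
#' @param true_ratio target/reference concentration ratio at the induced
#'   timepoint (the generating copy number when normalized to 0 hr).
#' @param ref_lambda reference concentration, copies per droplet, in
#'   (0, 5\].
#' @param n_droplets droplets per channel (>= 100; nominal 20000).
#' @param seed integer seed.
#' @param strain,locus,reference,time_hr labels for the emitted table.
#' @return data.frame in the droplet TSV schema (`strain`, `time_hr`,
#'   `locus`, `n_total`, `n_positive`) with four rows.
#' @export
generateDropletCounts <- function(true_ratio, ref_lambda = 1, n_droplets = 20000L,
                                  seed = 1L, strain = "synthetic", locus = "P2",
                                  reference = "ACT1", time_hr = 10) {
  if (ref_lambda <= 0 || ref_lambda > 5) stop("ref_lambda must lie in (0, 5]", call. = FALSE)
  if (true_ratio * ref_lambda <= 0) stop("target lambda must be > 0", call. = FALSE)
  if (n_droplets < 100) stop("n_droplets must be >= 100", call. = FALSE)
  withSeed(seed, {
    draw <- function(lambda) {
      stats::rbinom(1L, n_droplets, 1 - exp(-lambda))
    }
    data.frame(
      strain = strain,
      time_hr = c(0, 0, time_hr, time_hr),
      locus = c(locus, reference, locus, reference),
      n_total = n_droplets,
      n_positive = c(draw(ref_lambda), draw(ref_lambda),
                     draw(true_ratio * ref_lambda), draw(ref_lambda)),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic droplet time course
#'
#' Copy number follows a Boltzmann sigmoid from 1 to `plateau`; droplet
#' counts are drawn per timepoint as in [generateDropletCounts()].
#'
#' @param plateau top copy-number asymptote.
#' @param t_half,tau sigmoid midpoint and slope (hours).
#' @param times timepoints in hours (must include 0).
#' @param ref_lambda,n_droplets,seed,strain,locus,reference as in
#'   [generateDropletCounts()].
#' @return data.frame in the droplet TSV schema.
#' @export
generateDropletTimeCourse <- function(plateau = 1.7, t_half = 5, tau = 1,
                                      times = 0:10, ref_lambda = 1,
                                      n_droplets = 20000L, seed = 1L,
                                      strain = "synthetic", locus = "P2",
                                      reference = "ACT1") {
  stopifnot(0 %in% times)
  base <- 1
  cn <- base + (plateau - base) / (1 + exp((t_half - times) / tau))
  # anchor the curve so the 0-hr ratio is exactly 1 in expectation
  cn <- cn / (base + (plateau - base) / (1 + exp(t_half / tau)))
  withSeed(seed, {
    rows <- lapply(seq_along(times), function(i) {
      data.frame(
        strain = strain, time_hr = c(times[i], times[i]),
        locus = c(locus, reference), n_total = n_droplets,
        n_positive = c(
          stats::rbinom(1L, n_droplets, 1 - exp(-cn[i] * ref_lambda)),
          stats::rbinom(1L, n_droplets, 1 - exp(-ref_lambda))
        ),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Generate synthetic ChIP-qPCR quantification cycles
#'
#' Builds replicate Cq quadruples whose noiseless enrichment equals
#' `true_enrichment`: the target IP Cq is lowered by
#' `log2(true_enrichment)` relative to the identity configuration
#' (all four Cqs equal), then independent Gaussian noise of SD
#' `noise_sd` cycles is added to every Cq. Deterministic per seed.
#'
#' @param true_enrichment generating enrichment (> 0).
#' @param base_cq baseline quantification cycle.
#' @param noise_sd Gaussian Cq noise, cycles (>= 0).
#' @param n_replicates replicates.
#' @param input_dilution input dilution factor.
#' @param seed integer seed.
#' @param strain,locus,control_locus labels.
#' @return data.frame in the ChIP TSV schema.
#' @export
generateCq <- function(true_enrichment, base_cq = 25, noise_sd = 0.2,
                       n_replicates = 6, input_dilution = 10, seed = 1L,
                       strain = "synthetic", locus = "MAT",
                       control_locus = "ACT1") {
  if (true_enrichment <= 0) stop("true_enrichment must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  withSeed(seed, {
    noise <- function() stats::rnorm(n_replicates, 0, noise_sd)
    data.frame(
      strain = strain, locus = locus, control_locus = control_locus,
      replicate = seq_len(n_replicates),
      cq_ip_target = base_cq - log2(true_enrichment) + noise(),
      cq_input_target = base_cq + noise(),
      cq_ip_control = base_cq + noise(),
      cq_input_control = base_cq + noise(),
      input_dilution = input_dilution,
      stringsAsFactors = FALSE
    )
  })
}

GENOTYPES <- c("DNA2_VAR", "DNA2_pif1d", "dna2d_VAR", "dna2d_pif1d")

#' Generate synthetic meiotic spores under a viability model
#'
#' Each meiosis yields four spores with 2:2 segregation per marker
#' (`dna2::URA3` and `pif1::KANMX`); with the default recombination
#' fraction 0.5 the markers assort independently (tetrad patterns drawn
#' as independent 2:2 arrangements). Each spore then survives with its
#' genotype's viability probability; survivors are tallied by Ura and
#' G418 phenotype (Ura+ = `dna2` deletion; G418-resistant = `pif1::KANMX`).
#' RSA mode pools independent spores without tetrad grouping.
#' Deterministic per seed.
#'
#' @param viability named numeric vector over `DNA2_VAR`, `DNA2_pif1d`,
#'   `dna2d_VAR`, `dna2d_pif1d` (the PIF1-variant allele is whatever the
#'   cross carries: wild type or a mutant).
#' @param n_tetrads meioses to dissect (tetrad source).
#' @param n_spores spores to score (rsa source).
#' @param source `"tetrad"` or `"rsa"`.
#' @param seed integer seed.
#' @param recombination_fraction probability a spore's two markers are
#'   non-parental relative to each other (0.5 = unlinked; rsa mode only).
#' @return a [sporeTable()].
#' @export
generateSpores <- function(viability, n_tetrads = 35L, n_spores = 200L,
                           source = c("tetrad", "rsa"), seed = 1L,
                           recombination_fraction = 0.5) {
  source <- match.arg(source)
  if (!identical(sort(names(viability)), sort(GENOTYPES))) {
    stop("viability must be named over: ", paste(GENOTYPES, collapse = ", "),
         call. = FALSE)
  }
  if (any(viability < 0) || any(viability > 1)) {
    stop("viability probabilities must lie in [0,1]", call. = FALSE)
  }
  withSeed(seed, {
    if (source == "tetrad") {
      # each tetrad: independent 2:2 arrangement per marker
      dna2 <- replicate(n_tetrads, sample(c(TRUE, TRUE, FALSE, FALSE)))
      pif1 <- replicate(n_tetrads, sample(c(TRUE, TRUE, FALSE, FALSE)))
      dna2d <- as.vector(dna2)
      pif1d <- as.vector(pif1)
    } else {
      n <- n_spores
      dna2d <- stats::runif(n) < 0.5
      parental <- stats::runif(n) >= recombination_fraction
      # parental configurations pair dna2::URA3 with pif1::KANMX
      pif1d <- ifelse(parental, dna2d, !dna2d)
    }
    geno <- paste0(ifelse(dna2d, "dna2d", "DNA2"), "_",
                   ifelse(pif1d, "pif1d", "VAR"))
    survives <- stats::runif(length(geno)) < viability[geno]
    g <- geno[survives]
    cnt <- function(k) sum(g == k)
    sporeTable(
      ura_plus_g418s = cnt("dna2d_VAR"),
      ura_plus_g418r = cnt("dna2d_pif1d"),
      ura_minus_g418s = cnt("DNA2_VAR"),
      ura_minus_g418r = cnt("DNA2_pif1d"),
      source = source,
      n_tetrads = if (source == "tetrad") n_tetrads else NA_integer_
    )
  })
}
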