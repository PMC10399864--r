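---
title: "Statistical models behind the BIR assay toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical models behind the BIR assay toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BIRquant)
```

BIRquant implements the statistics of a family of yeast break-induced
replication (BIR) assays built on a disomic chromosome III strain: a
galactose-inducible HO endonuclease cuts the truncated recipient copy
of chromosome III, and repair against the full-length donor is read out
at the colony, rate, molecule and protein level. This vignette explains
each model, the parameters that matter, what the synthetic generators
do and do not emulate, and the design choices made where the design was
genuinely open.

## Repair-outcome decomposition

Each plated cell resolves its DSB by one mechanism, and two genetic
markers partition colonies into classes: Ade+ Leu- (the pool), Ade+
Leu+ (gene conversion), Ade-red Leu- (chromosome loss), Ade-white Leu-
(half-crossover class I). Two contaminants hide inside the Ade+ Leu-
pool:

* **GCRs.** A sample of pool colonies is karyotyped by CHEF gel
  electrophoresis; the rearranged fraction is a binomial estimate
  applied to the whole pool. `estimateGcrFraction()` attaches an exact
  Clopper-Pearson 95% CI — chosen over asymptotic intervals because the
  karyotyped samples are small (tens of colonies), where Wald-type
  intervals undercover badly.
* **HC-II.** A half-crossover chromosome fuses the recipient's
  ADE1-proximal part to donor sequence. At the next mitosis it
  segregates with one of the two intact chromatids: with a full-length
  donor the daughter is phenotypically Ade+ Leu- (HC-II); with the
  truncated recipient it is Ade-white Leu- (HC-I). Both scenarios
  involve one repaired and one lost chromatid, and under random
  segregation they are equiprobable, so the HC-II count is imputed as
  equal to the observed HC-I count. `enumerateHcSegregation()` returns
  the scenario table and the resulting HC-II fraction — exactly 1/2 at
  the default weight, and equal to the weight `w` in general, which
  lets the sensitivity of downstream numbers to the equal-segregation
  assumption be probed directly.

`decomposeOutcomes()` then computes
`BIR = pool - f_GCR * pool - HC_I`. The GCR term is kept real-valued
(a fraction applied to a count); `percentDisplay()` rounds half away
from zero for display, which is what makes 10/23 print as 43% and 1/30
as 3%. If the two corrections exceed the pool the BIR count is floored
at zero and the result flagged `bir_floored` rather than silently
truncated — with the flag set, count conservation is restored by the
recorded deficit. Frequencies are reported over *all* scored colonies,
including the unclassified `other` class; the denominator is stored in
the object so any alternative convention can be recomputed.

Strain comparisons (`compareDistributions()`) use the chi-square test
of homogeneity for multi-class tables and Fisher's exact test for
2x2 tables. The choice is recorded in the returned `method`: exact
conditional inference is feasible and preferable at 2x2 with small
karyotyping counts, while the multi-class colony tables have hundreds
of colonies per strain where chi-square is standard.

## The segregation simulator

`simulateColonies()` is the phenotype-level generative model: each
colony draws its mechanism from `(p_bir, p_gc, p_hc, p_cl, p_gcr,
p_other)` and HC colonies flip a coin with weight `w` between HC-II
(scored Ade+ Leu-) and HC-I. The model is deliberately not molecular —
chromatid identities appear only through the two enumerated scenarios,
and each cell repairs exactly one broken chromatid. The expected
Ade+ Leu- fraction is `p_bir + p_gcr + p_hc * w`
(`expectedPhenotypeProbs()`), which the test suite verifies by
goodness-of-fit at n = 1e5, and decomposing simulated counts with the
generator's own GCR fraction recovers `p_bir` — the end-to-end
validation of the imputation logic. Colony viability is assumed equal
across classes; if, say, HC colonies plated less efficiently, observed
HC-I would underestimate HC-II and the decomposition would overcount
BIR. No per-class plating-efficiency data exist to calibrate this.

## Mutagenesis rates

The `lys2::A4` reporter sits 16 kb from the DSB on the donor; BIR
synthesis across it is highly error-prone, so Lys+ reversion frequency
after a 7-hr induction, minus the pre-induction background, measures
how often BIR reaches 16 kb. The per-replicate frequency is
`(Lys+ colonies x selective dilution) / (viable colonies x permissive
dilution)`, invariant to proportional dilution changes.

`estimateRate()` centres replicate frequencies with the **mean** by
default. The alternative — the median, traditional in fluctuation
assays as protection against jackpot cultures — breaks down here: in
this protocol mutations arise during the induction window rather than
by clonal expansion, so replicate counts are close to Poisson and
jackpots are not expected; and at mutant rates the expected count per
culture is of order one (a 1.4e-7 rate at 1e7 cells plated gives ~1.4
colonies), where the median collapses onto the integer grid and is
biased low by tens of percent. The mean is the Poisson MLE and remains
unbiased there. `center = "median"` is available for data where
jackpots are a genuine concern. Negative net rates (background above
induced) are reported with a `negative_net_rate` flag, never clamped,
so simulation studies see the estimator's true sampling distribution.

Uncertainty is a seeded percentile bootstrap over replicate cultures
(default 2000 resamples), resampled independently per timepoint;
`foldChange()` bootstraps both strains jointly for the ratio CI. Strain
comparisons use the two-sided Mann-Whitney U test, exact for small
tie-free samples.

## AMBER ddPCR quantification

Poisson partitioning of template into `n` droplets makes the positive
fraction `p = 1 - exp(-lambda)`, so `lambda = -ln(1 - k/n)`. The 95% CI
on lambda is the Clopper-Pearson interval on `p` pushed through the
same monotone transform. A fully positive channel is rejected as
saturated rather than returning an infinite estimate. The
target/reference (ACT1) ratio divides the two lambdas; because no
propagation convention is standard for the published error bars, the
default CI divides the per-channel bounds conservatively
(`t_low/r_high`, `t_high/r_low`), and a first-order delta-method
interval on the log ratio is available via `ci_method = "delta"` — at
20,000 droplets the two differ by little, as the tests check.

Copy number normalizes each locus's ratio to its own 0-hr ratio: 1x
before BIR, at most 2x after full donor replication. Estimates are not
clamped to [1, 2]; the bounds are properties of the expectation, not of
noisy estimates. Synthesis is called at >= 1.1x — inclusive, on the
point estimate by default, with `require_ci = TRUE` demanding the whole
CI clear the threshold (at 20,000 droplets the point-estimate call has
a negligible false-positive rate at a true ratio of 1, which the test
suite bounds at 5%).

Time courses are summarized by the Boltzmann sigmoid
`y(t) = base + (top - base)/(1 + exp((t_half - t)/tau))`, fit by
Levenberg-Marquardt least squares with data-driven starts (`base =
min(y)`, `top = max(y)`, `t_half` at the mid-range crossing, `tau = 1`
hr) and `tau` bounded to (0.01, 20] hours to keep the curve
identifiable on an 11-point, 10-hour course. Constant or degenerate
series return `converged = FALSE` with best-effort parameters.
`maxCopyNumber()` reports the per-locus maximum over the course, which
can exceed the terminal value when interrupted BIR products degrade
late — the reason maxima, not endpoints, are compared across strains.

## ChIP-qPCR enrichment

Per replicate, percent-of-input is `dilution * 2^(Cq_input - Cq_ip)`
for the target and for its control locus (ACT1 for MAT; YBL028C for
CEN13 and mtDNA), and enrichment is their ratio, in which the dilution
and any global Cq shift cancel. Amplification efficiency is fixed at
2.0 — no standard-curve calibration is modelled — but exposed as a
parameter. Because the control-locus normalization applies to both IP
and input, this percent-input ratio coincides with a delta-delta-Cq
fold up to a constant that cancels in strain ratios, so the choice
between the two conventions does not affect `foldReduction()`, which
reports the ratio of mean enrichments with a Welch unpaired t-test.

## Suppression genetics

In `DNA2/dna2::URA3 x PIF1-variant/pif1::KANMX` crosses, Ura+ spores
are `dna2` deletions and G418 resistance marks `pif1::KANMX`, so Ura+
G418-sensitive colonies are `dna2` deletions kept alive by the PIF1
variant alone. `suppressionFraction()` is the binomial fraction of
sensitive among Ura+ spores with a Clopper-Pearson CI. Exact binomial
tests (two-sided by doubling the smaller tail, capped at 1 — chosen
over the minimum-likelihood two-sided rule for its transparency at the
tiny printed counts) cover the 1:1 Mendelian control among Ura- spores
and suppression against two nulls: 0 (no rescue, the wild-type
expectation, handled as a degenerate flagged case) and 0.5 (parity with
the `dna2 pif1` double deletion). The two markers are treated as
unlinked (no linkage information is available; the generator exposes a
recombination fraction defaulting to 0.5).

## Synthetic generators

Every generator takes a single integer seed, restores the caller's RNG
state, and is byte-deterministic given seed and parameters. Noise
models follow the physical sampling process: Poisson for colony and
droplet counts, Gaussian for Cq values (default SD 0.2 cycles, a
typical qPCR replicate spread), 2% relative Gaussian error on
permissive-plate viable counts (pipetting/plating noise; configurable,
as no measured value exists). Defaults are the study conditions: 20
replicate cultures of 1e7 cells for plating, 20,000 droplets per
channel, 6 ChIP replicates, 35-tetrad dissections.

What the generators do **not** emulate: clonal jackpot expansion of
pre-induction Lys+ mutants (the 0-hr background is an independent
frequency); droplet-volume variation and rain in ddPCR; qPCR
efficiency drift; meiotic linkage beyond a single recombination
fraction; per-class colony viability differences. Passing
parameter-recovery tests therefore show the estimators are correct
under the assays' idealized sampling models, not that they are robust
to these instrument- and biology-level artifacts.

## Problem sizes and numerical choices

The test suite runs parameter recovery at the assays' own scale — 20
cultures x 1e7 cells over 20 seeds for rates and the 27-fold WT/mutant
ratio (tolerances 15% and 20% on the medians), 20,000 droplets over 20
seeds for the 1.7x copy-number recovery (tolerance 0.05) — and
Monte-Carlo coverage checks at 200-1000 replicates with a >= 90-93%
bound on nominal 95% intervals, a deliberately loose bound that keeps
the checks cheap and stable. The acceptance script uses 100 seeds for
the fold recovery and 30 for copy number, reporting medians across
seeds. Exact oracles (hypergeometric enumeration for Fisher's test,
rank-assignment enumeration for Mann-Whitney at 4 vs 4, brute-force
window scanning for the NLS consensus) are implemented independently in
the test helpers and agree with the package to 1e-10.

Other numerical conventions: probability vectors must sum to 1 within
1e-12; decomposition frequencies sum to 1 within 1e-9 unless flooring
occurred; percent display rounds half away from zero; protein
coordinates are 1-based and inclusive throughout, with sequence anchors
carrying full-protein numbering, and the consensus spacer X admits all
20 residues (including K and R). Ambiguity codes are rejected at
construction because the consensus is undefined for them.

## Known limitations

The GCR correction treats the karyotyped sample as representative of
the whole Ade+ Leu- pool and ignores its sampling error when
subtracting (the CI is reported but not propagated into the BIR count).
The HC-II imputation is exactly as good as the equal-segregation
premise. The rate estimator is a frequency difference over a fixed
window, not a fluctuation-analysis estimator, and assumes equal
effective cell numbers across timepoints. The Boltzmann fit is a
summary curve, not a mechanistic model of BIR elongation.
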