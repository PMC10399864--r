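# BIRquant

Quantitative analysis of break-induced replication (BIR) assays in
budding yeast.

When a double-strand break (DSB) has homology on only one side — at an
eroded telomere, a collapsed fork, or the truncated chromosome III of
the AM1003 disomic assay strain — repair proceeds by BIR: the broken
end invades the intact homolog and copies it, sometimes for ~100 kb, to
the chromosome end. BIR is efficient but dangerous: it is highly
mutagenic, and interrupted BIR yields half-crossovers (HC) and gross
chromosomal rearrangements (GCR). Studies of BIR factors (the Pif1
helicase and its nuclear-localization-signal mutants among them) rely
on a family of interlocking assays whose statistics this package
implements:

* **Repair-outcome accounting.** Colonies are scored by two markers:
  Ade+ Leu- (completed BIR pool), Ade+ Leu+ (gene conversion, GC),
  Ade-red Leu- (chromosome loss, CL), Ade-white Leu- (half-crossover
  class I, HC-I). The Ade+ Leu- pool is then decomposed: a GCR fraction
  estimated by CHEF karyotyping of a colony sample is applied to the
  pool, the invisible HC-II class is imputed as HC-II = HC-I, and the
  remainder is completed BIR:

  `BIR = N(Ade+Leu-) - f_GCR * N(Ade+Leu-) - N(HC-I)`

  The imputation rests on a segregation argument: an HC chromosome
  co-segregates at mitosis with an intact donor chromatid half the
  time, producing Ade+ Leu- daughters indistinguishable from BIR.
  `enumerateHcSegregation()` derives the factor 1/2 from the two-scenario
  model; `simulateColonies()` is the matching colony-level generator.
* **BIR-associated mutagenesis.** A `lys2::A4` frameshift reporter 16 kb
  from the DSB reverts at rate `f = (Lys+ colonies x selective dilution) /
  (viable colonies x permissive dilution)`; the pre-induction (0-hr)
  background is subtracted and strains are compared by fold-change and
  Mann-Whitney tests.
* **AMBER ddPCR kinetics.** Template molecules partitioned into ~20,000
  droplets give `lambda = -ln(1 - k/n)` copies per droplet; donor copy
  number is the target/ACT1 ratio normalized to 0 hr (1x before BIR,
  at most 2x after), synthesis is called at >= 1.1x, and time courses
  are summarized by a Boltzmann sigmoid
  `y(t) = base + (top-base)/(1 + exp((t_half - t)/tau))`.
* **ChIP-qPCR enrichment** (percent-of-input ratios with Welch t-tests)
  and **dna2-deletion suppression genetics** (tetrad and random-spore
  counts with exact binomial tests) round out the toolkit.
* **Seeded synthetic-data generators** emulate every assay (multinomial
  colony counts, Poisson Lys+ and droplet counts, Gaussian Cq noise,
  2:2 tetrad segregation with genotype-dependent viability), so the
  whole pipeline is testable with no external data.

## Worked example

```r
library(BIRquant)
fx <- assayFixtures()   # printed counts, sequences and assay constants

# 1. The monopartite NLS candidate contains one consensus match
scanMonopartiteNLS(fx$sequences$monopartite_candidate)
#>                       seq_id start end matched      pattern_id
#> 1 Pif1-monopartite-candidate   781 784    KKRK K-(K/R)-X-(K/R)

# 2. GCR fraction among Ade+Leu- colonies of the pif1 deletion (CHEF: 10/23)
gMut <- estimateGcrFraction(10, 23)
gMut
#> GcrEstimate: 10/23 rearranged = 0.4348 (43%), 95% CI [0.2319, 0.6551]

# 3. Decompose a colony table with that GCR fraction
d <- decomposeOutcomes(
  PhenotypeCounts(150, gc = 16, cl = 18, hc_i = 8, other = 8, label = "pif1d"),
  gMut
)
d
#> OutcomeDecomposition [pif1d], 200 colonies
#>          gc cl hc_i hc_ii   gcr   bir other
#> count    16 18    8     8 65.22 76.78     8
#> freq (%)  8  9    4     4 32.60 38.40     4

# 4. Mutagenesis rate from a synthetic plating experiment at 3.9e-6 per cell
pl <- generatePlating(3.9e-6, 1e-8, n_cultures = 20, seed = 42, strain = "WT")
estimateRate(pl$t7, pl$t0, seed = 42)
#> RateEstimate [WT]: net 4.01e-06 per cell (induced 4.04e-06 - background 2.47e-08)
#>   95% bootstrap CI [3.67e-06, 4.33e-06], 20 replicates

# 5. ddPCR copy number from synthetic droplets generated at 1.7x
ser <- copyNumberSeries(generateDropletCounts(1.7, seed = 42))
round(ser[ser$time_hr == 10, c("ratio", "copy_number", "ci_low", "ci_high")], 3)
#>   ratio copy_number ci_low ci_high
#> 2 1.679       1.653  1.595   1.713
callSynthesis(1.7)
#> [1] TRUE
```

The decomposition in step 3 reads: of 150 Ade+ Leu- colonies, 43.48%
(65.2) are attributed to GCR, 8 to the imputed HC-II class, and the
remaining 76.8 to completed BIR — 38.4% of all 200 scored colonies.

## Documentation

See the methods vignette (`vignettes/bir-assay-statistics.Rmd`) for the
models, their assumptions, the default parameter choices and the
limitations of the synthetic generators.
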