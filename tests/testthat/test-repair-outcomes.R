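test_that("colony phenotypes map deterministically onto repair classes", {
  expect_equal(classifyColony("minus_red", "minus"), "CL")
  expect_equal(classifyColony("minus_white", "minus"), "HC_I")
  expect_equal(classifyColony("plus", "plus"), "GC")
  expect_equal(classifyColony("plus", "minus"), "ADE_PLUS_LEU_MINUS")
  expect_equal(classifyColony("minus_red", "plus"), "OTHER")
  expect_equal(classifyColony("minus_white", "plus"), "OTHER")
  expect_error(classifyColony("pink", "minus"), "unknown ade")
  expect_error(classifyColony("plus", "maybe"), "unknown leu")
})

test_that("tallyColonies aggregates the colony TSV schema", {
  tab <- data.frame(
    strain = "WT",
    ade_phenotype = c("plus", "plus", "minus_red", "minus_white", "plus"),
    leu_phenotype = c("minus", "plus", "minus", "minus", "minus"),
    count = c(70, 5, 9, 4, 5)
  )
  pc <- tallyColonies(tab)
  expect_equal(unname(phenotypeCounts(pc)), c(75L, 5L, 9L, 4L, 0L))
  expect_equal(totalColonies(pc), 93L)
})

test_that("GCR fraction matches the printed CHEF percentages", {
  g <- estimateGcrFraction(10, 23)
  expect_equal(gcrFraction(g), 10 / 23, tolerance = 1e-12)
  expect_equal(percentDisplay(gcrFraction(g)), 43)
  g2 <- estimateGcrFraction(1, 30)
  expect_equal(round(gcrFraction(g2), 4), 0.0333)
  expect_equal(percentDisplay(gcrFraction(g2)), 3)
  g0 <- estimateGcrFraction(0, 25)
  expect_equal(gcrFraction(g0), 0)
  expect_equal(g0@ci_low, 0)
  expect_error(estimateGcrFraction(1, 0), ">= 1")
})

test_that("Clopper-Pearson bounds agree with binom.test", {
  for (case in list(c(10, 23), c(1, 30), c(0, 25), c(8, 42))) {
    ours <- clopperPearson(case[1], case[2])
    ref <- binom.test(case[1], case[2])$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("decomposition follows the GCR correction and HC-II imputation", {
  d <- decomposeOutcomes(PhenotypeCounts(100, gc = 5, cl = 20, hc_i = 10), 0.30)
  cnt <- decompositionCounts(d)
  expect_equal(cnt[["gcr"]], 30)
  expect_equal(cnt[["hc_ii"]], 10)
  expect_equal(cnt[["bir"]], 60)
  expect_equal(decompositionFrequencies(d)[["bir"]], 60 / 135)
  expect_equal(sum(decompositionFrequencies(d)), 1, tolerance = 1e-12)
  # no corrections: the whole pool is BIR
  d0 <- decomposeOutcomes(PhenotypeCounts(40, gc = 1, cl = 2, hc_i = 0), 0)
  expect_equal(decompositionCounts(d0)[["bir"]], 40)
  # over-correction floors BIR at zero with a flag
  df <- decomposeOutcomes(PhenotypeCounts(10, hc_i = 20), 0.5)
  expect_equal(decompositionCounts(df)[["bir"]], 0)
  expect_true("bir_floored" %in% df@flags)
})

test_that("decomposition conserves counts and is scale-equivariant", {
  set.seed(31)
  for (i in 1:20) {
    pool <- sample(0:200, 1)
    hc <- sample(0:50, 1)
    frac <- runif(1)
    pc <- PhenotypeCounts(pool, gc = sample(0:30, 1), cl = sample(0:60, 1),
                          hc_i = hc, other = sample(0:10, 1))
    d <- decomposeOutcomes(pc, frac)
    cnt <- decompositionCounts(d)
    deficit <- max(0, frac * pool + hc - pool)
    expect_equal(cnt[["gcr"]] + cnt[["hc_ii"]] + cnt[["bir"]] - deficit, pool,
                 tolerance = 1e-9)
    if (!length(d@flags)) {
      expect_equal(sum(decompositionFrequencies(d)), 1, tolerance = 1e-9)
      # scaling all counts by c scales class counts and fixes frequencies
      k <- sample(2:5, 1)
      pcK <- PhenotypeCounts(pool * k, gc = phenotypeCounts(pc)[["gc"]] * k,
                             cl = phenotypeCounts(pc)[["cl"]] * k,
                             hc_i = hc * k,
                             other = phenotypeCounts(pc)[["other"]] * k)
      dK <- decomposeOutcomes(pcK, frac)
      expect_equal(decompositionCounts(dK), cnt * k, tolerance = 1e-9)
      expect_equal(decompositionFrequencies(dK), decompositionFrequencies(d),
                   tolerance = 1e-9)
    }
  }
})

test_that("2x2 comparisons use Fisher and match hypergeometric enumeration", {
  res <- compareDistributions(c(10, 13), c(1, 29))
  expect_match(res$method, "Fisher")
  tab <- cbind(c(10, 13), c(1, 29))
  expect_equal(res$p.value, oracleFisher2x2(tab), tolerance = 1e-10)
  set.seed(5)
  for (i in 1:10) {
    a <- sample(0:20, 2) + c(1, 0)
    b <- sample(0:20, 2) + c(0, 1)
    res <- compareDistributions(a, b)
    expect_equal(res$p.value, oracleFisher2x2(cbind(a, b)), tolerance = 1e-10)
  }
})

test_that("multi-class comparisons use chi-square homogeneity", {
  a <- PhenotypeCounts(75, gc = 8, cl = 9, hc_i = 4, other = 4)
  b <- PhenotypeCounts(150, gc = 16, cl = 18, hc_i = 8, other = 8)
  res <- compareDistributions(a, b)
  expect_match(res$method, "chi-square")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1, tolerance = 1e-12)
  # permuting class labels leaves the statistic unchanged
  x <- c(30, 10, 5, 20, 2)
  y <- c(12, 25, 7, 9, 4)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(compareDistributions(x, y)$statistic,
               compareDistributions(x[perm], y[perm])$statistic,
               tolerance = 1e-12)
  expect_error(compareDistributions(c(0, 0), c(0, 0)), ">= 1")
})
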