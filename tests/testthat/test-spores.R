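test_that("suppression fractions reproduce the printed spore ratios", {
  rsa <- suppressionFraction(8, 34)
  expect_equal(round(rsa$fraction, 3), 0.190)
  tet <- suppressionFraction(3, 24)
  expect_equal(round(tet$fraction, 3), 0.111)
  # a cross with no rescued class: fraction 0, CI excluding parity
  none <- suppressionFraction(0, 24)
  expect_equal(none$fraction, 0)
  expect_lt(none$ci_high, 0.5)
  expect_error(suppressionFraction(0, 0), ">= 1 Ura")
  # CP interval agrees with binom.test
  ref <- binom.test(8, 42)$conf.int
  expect_equal(c(rsa$ci_low, rsa$ci_high), as.numeric(ref), tolerance = 1e-10)
})

test_that("Mendelian control test is exact, symmetric and closed-form", {
  expect_equal(testMendelianControl(10, 10)$p.value, 1)
  expect_equal(testMendelianControl(0, 20)$p.value, 2 * 0.5^20, tolerance = 1e-12)
  set.seed(43)
  for (i in 1:10) {
    s <- sample(0:30, 1)
    r <- sample(0:30, 1)
    if (s + r == 0) next
    expect_equal(testMendelianControl(s, r)$p.value,
                 testMendelianControl(r, s)$p.value, tolerance = 1e-12)
  }
})

test_that("suppression test handles both nulls including the degenerate one", {
  # no rescued spores among 24 against full-suppression parity
  expect_equal(testSuppression(0, 0.5, n_g418r = 24)$p.value, 2 * 0.5^24,
               tolerance = 1e-12)
  expect_equal(testSuppression(12, 0.5, n_g418r = 12)$p.value, 1)
  # observing any rescued spore refutes a null of exactly zero
  deg <- testSuppression(8, 0, n_g418r = 34)
  expect_equal(deg$p.value, 0)
  expect_true("null_degenerate" %in% deg$flags)
  expect_equal(testSuppression(0, 0, n_g418r = 24)$p.value, 1)
  expect_error(testSuppression(8, 1, n_g418r = 34), "\\[0, 1\\)")
  # sporeTable input wires the Ura+ classes through
  tab <- sporeTable(3, 24, 17, 18, source = "tetrad", n_tetrads = 35)
  expect_equal(testSuppression(tab, 0.5)$n_s, 3)
  expect_equal(suppressionFraction(tab)$n_total, 27)
  expect_equal(testMendelianControl(tab)$n_total, 35)
})

test_that("sporeTable enforces the tetrad spore budget", {
  expect_error(sporeTable(50, 50, 50, 50, source = "tetrad", n_tetrads = 10),
               "4 x n_tetrads")
  expect_error(sporeTable(1, 1, 1, 1, source = "tetrad"), "n_tetrads")
  expect_silent(sporeTable(1, 1, 1, 1, source = "rsa"))
})

test_that("tetrad generator conserves spores with 2:2 marker segregation", {
  allAlive <- c(DNA2_VAR = 1, DNA2_pif1d = 1, dna2d_VAR = 1, dna2d_pif1d = 1)
  st <- generateSpores(allAlive, n_tetrads = 50, source = "tetrad", seed = 2)
  expect_equal(sum(st$counts), 200L)
  # 2:2 per marker: each marker class is exactly half of all spores
  expect_equal(st$counts[["ura_plus_g418s"]] + st$counts[["ura_plus_g418r"]], 100L)
  expect_equal(st$counts[["ura_plus_g418s"]] + st$counts[["ura_minus_g418s"]], 100L)
})

test_that("spore generator respects the viability model and the seed", {
  # lethal dna2-deletion + PIF1-variant class: no Ura+ G418-sensitive spores
  wtLike <- c(DNA2_VAR = 1, DNA2_pif1d = 1, dna2d_VAR = 0, dna2d_pif1d = 1)
  st <- generateSpores(wtLike, n_tetrads = 36, source = "tetrad", seed = 4)
  expect_equal(st$counts[["ura_plus_g418s"]], 0L)
  expect_gt(st$counts[["ura_plus_g418r"]], 0L)
  s1 <- generateSpores(wtLike, n_spores = 300, source = "rsa", seed = 9)
  s2 <- generateSpores(wtLike, n_spores = 300, source = "rsa", seed = 9)
  expect_identical(s1$counts, s2$counts)
  expect_error(generateSpores(c(A = 1)), "named")
})

test_that("full viability reproduces Mendelian class expectations", {
  allAlive <- c(DNA2_VAR = 1, DNA2_pif1d = 1, dna2d_VAR = 1, dna2d_pif1d = 1)
  st <- generateSpores(allAlive, n_spores = 4000, source = "rsa", seed = 21)
  n <- sum(st$counts)
  expect_equal(n, 4000L)
  se <- sqrt(4000 * 0.25 * 0.75)
  for (cls in names(st$counts)) {
    expect_lte(abs(st$counts[[cls]] - 1000), 3 * se)
  }
})

test_that("suppression CI covers the generating conditional fraction", {
  # viability model: rescued class survives at 0.2, double deletion at 1
  model <- c(DNA2_VAR = 1, DNA2_pif1d = 1, dna2d_VAR = 0.2, dna2d_pif1d = 1)
  trueFrac <- 0.2 / (0.2 + 1)
  hits <- vapply(1:200, function(s) {
    st <- generateSpores(model, n_spores = 400, source = "rsa", seed = s)
    ci <- suppressionFraction(st)
    ci$ci_low <= trueFrac && trueFrac <= ci$ci_high
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})
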