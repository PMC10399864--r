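test_that("lambda follows the Poisson correction exactly", {
  expect_equal(lambdaFromDroplets(0, 20000)$lambda, 0)
  expect_equal(lambdaFromDroplets(10000, 20000)$lambda, log(2), tolerance = 1e-12)
  expect_error(lambdaFromDroplets(20000, 20000), "saturated")
  expect_error(lambdaFromDroplets(5, 0), ">= 1")
  # strictly increasing in n_positive, CI brackets the estimate
  lam <- lambdaFromDroplets(0:19999, 20000)
  expect_true(all(diff(lam$lambda) > 0))
  expect_true(all(lam$ci_low <= lam$lambda + 1e-12))
  expect_true(all(lam$lambda <= lam$ci_high + 1e-12))
})

test_that("lambda CI covers the generating concentration", {
  trueLambda <- 0.8
  n <- 20000
  set.seed(101)
  pos <- rbinom(1000, n, 1 - exp(-trueLambda))
  lam <- lambdaFromDroplets(pos, n)
  coverage <- mean(lam$ci_low <= trueLambda & trueLambda <= lam$ci_high)
  expect_gte(coverage, 0.93)
})

test_that("ratio estimation and its CI behave on known channels", {
  ch <- dropletChannel("P2", 12000, 20000)
  self <- ratioWithCI(ch, ch)
  expect_equal(self$ratio, 1)
  expect_lte(self$ci_low, 1)
  expect_gte(self$ci_high, 1)
  # lambda_t exactly twice lambda_r
  lamR <- 0.4
  r <- dropletChannel("ACT1", round(20000 * (1 - exp(-lamR))), 20000)
  t2 <- dropletChannel("P2", round(20000 * (1 - exp(-2 * channelLambda(r)))), 20000)
  expect_equal(ratioWithCI(t2, r)$ratio, 2, tolerance = 1e-3)
  zero <- dropletChannel("ACT1", 0, 20000)
  expect_error(ratioWithCI(ch, zero), "> 0")
  # CI width shrinks roughly as 1/sqrt(n)
  width <- function(n, seed) {
    set.seed(seed)
    tgt <- dropletChannel("P2", rbinom(1, n, 1 - exp(-1.5)), n)
    ref <- dropletChannel("ACT1", rbinom(1, n, 1 - exp(-1)), n)
    ci <- ratioWithCI(tgt, ref)
    ci$ci_high - ci$ci_low
  }
  w5k <- mean(vapply(1:20, function(s) width(5000, s), 0))
  w20k <- mean(vapply(1:20, function(s) width(20000, 100 + s), 0))
  expect_equal(w5k / w20k, 2, tolerance = 0.25)
  # point estimate near the generating ratio and inside its own CI
  set.seed(7)
  tgt <- dropletChannel("P2", rbinom(1, 20000, 1 - exp(-1.5)), 20000)
  ref <- dropletChannel("ACT1", rbinom(1, 20000, 1 - exp(-1)), 20000)
  est <- ratioWithCI(tgt, ref)
  expect_gte(est$ratio, est$ci_low)
  expect_lte(est$ratio, est$ci_high)
  expect_lt(abs(est$ratio - 1.5), 0.1)
  # the delta-method alternative agrees closely at large n
  delta <- ratioWithCI(tgt, ref, ci_method = "delta")
  expect_equal(delta$ratio, est$ratio)
  expect_lt(abs(delta$ci_low - est$ci_low), 0.02)
})

test_that("copy numbers normalize to the 0-hr ratio per locus", {
  mkRow <- function(t, locus, lambda) {
    data.frame(strain = "WT", time_hr = t, locus = locus, n_total = 20000L,
               n_positive = as.integer(round(20000 * (1 - exp(-lambda)))))
  }
  tab <- rbind(
    mkRow(0, "P2", 1), mkRow(0, "ACT1", 1),
    mkRow(5, "P2", 1.7), mkRow(5, "ACT1", 1)
  )
  ser <- copyNumberSeries(tab)
  expect_equal(ser$copy_number[ser$time_hr == 0], 1)
  expect_equal(ser$copy_number[ser$time_hr == 5], 1.7, tolerance = 5e-3)
  # all ratios equal: flat copy number 1
  flat <- rbind(mkRow(0, "P2", 1.2), mkRow(0, "ACT1", 1.2),
                mkRow(3, "P2", 0.9), mkRow(3, "ACT1", 0.9))
  expect_equal(copyNumberSeries(flat)$copy_number, c(1, 1), tolerance = 1e-12)
  # missing 0-hr sample is an error
  expect_error(copyNumberSeries(rbind(mkRow(5, "P2", 1), mkRow(5, "ACT1", 1))),
               "0-hr")
})

test_that("the synthesis call threshold is 1.1x inclusive", {
  expect_false(callSynthesis(1.09))
  expect_true(callSynthesis(1.10))
  expect_true(callSynthesis(1.7))
  expect_equal(callSynthesis(c(0, 1.0999, 1.1, 2)), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(callSynthesis(1.5, ci_low = 1.2, require_ci = TRUE))
  expect_false(callSynthesis(1.5, ci_low = 1.05, require_ci = TRUE))
  expect_error(callSynthesis(1.5, require_ci = TRUE), "ci_low")
  expect_error(callSynthesis(-0.1), ">= 0")
})

test_that("Boltzmann fit recovers noiseless parameters and flags degeneracy", {
  t <- 0:10
  y <- 1 + (1.7 - 1) / (1 + exp((5 - t) / 1))
  fit <- fitBoltzmann(t, y)
  expect_true(fit@converged)
  expect_lt(fit@rss, 1e-10)
  expect_equal(fit@base, 1, tolerance = 1e-4)
  expect_equal(fit@top, 1.7, tolerance = 1e-4)
  expect_equal(fit@t_half, 5, tolerance = 1e-4)
  expect_equal(fit@tau, 1, tolerance = 1e-4)
  expect_gt(fit@tau, 0)
  # fitted curve is monotone nondecreasing when top >= base
  pred <- predictBoltzmann(fit, seq(0, 10, by = 0.1))
  expect_true(all(diff(pred) >= -1e-12))
  # constant series: degenerate flat fit or non-convergence
  flat <- fitBoltzmann(t, rep(1, 11))
  expect_true(abs(flat@top - flat@base) < 1e-6 || !flat@converged)
  expect_error(fitBoltzmann(0:3, rep(1, 4)), ">= 5 points")
  expect_error(fitBoltzmann(c(0, 1, 2, 2.5, 3), rep(1, 5)), "span")
})

test_that("maxCopyNumber reports the per-locus maximum with its timepoint", {
  ser <- data.frame(locus = "P2", time_hr = c(0, 2, 4, 10),
                    copy_number = c(1.0, 1.2, 1.3, 1.15))
  mx <- maxCopyNumber(ser)
  expect_equal(mx$max_copy_number, 1.3)
  expect_equal(mx$time_hr, 4)
  mono <- data.frame(locus = "P3", time_hr = 0:3,
                     copy_number = c(1, 1.1, 1.3, 1.6))
  expect_equal(maxCopyNumber(mono)$time_hr, 3)
  # the maximum over the course is never below the terminal value
  set.seed(19)
  for (i in 1:10) {
    s <- data.frame(locus = "P2", time_hr = 0:10, copy_number = runif(11, 1, 2))
    expect_gte(maxCopyNumber(s)$max_copy_number,
               s$copy_number[s$time_hr == 10])
  }
  expect_error(maxCopyNumber(ser[0, ]), "empty")
})
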