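test_that("summary statistics match closed forms", {
  s <- summaryStat(1:5)
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2.5))          # ~1.5811
  expect_equal(s$se, sqrt(2.5) / sqrt(5))  # ~0.7071
  expect_equal(s$n, 5L)
  z <- summaryStat(c(5, 5, 5))
  expect_equal(z$sd, 0)
  expect_equal(z$se, 0)
  one <- summaryStat(42)
  expect_true(one$singleValue)
  expect_error(summaryStat(numeric()), "no values")
})

test_that("relative error against the theoretical value is as printed", {
  expect_equal(relativeError(83.7, 90), 7.0, tolerance = 1e-9)
  expect_equal(relativeError(90, 90), 0.0)
  expect_equal(relativeError(45, 90), 50.0)
  expect_error(relativeError(1, 0), "nonzero")
})

test_that("the pooled t-test matches the closed form to 1e-9", {
  a <- c(1.1, 0.9, 1.3)
  b <- c(0.2, 0.4, 0.1)
  got <- studentTTest(a, b)
  ## independent closed form: pooled variance, exact t distribution tails
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
         (length(a) + length(b) - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  pval <- 2 * pt(-abs(tstat), df = length(a) + length(b) - 2)
  expect_equal(got$statistic, tstat, tolerance = 1e-9)
  expect_equal(got$p.value, pval, tolerance = 1e-9)
  expect_identical(got$df, 4)
})

test_that("t-test degenerate and trivial branches behave as defined", {
  same <- studentTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_identical(same$label, "ns")
  z <- studentTTest(c(0, 1), c(0, 1))
  expect_equal(z$statistic, 0)
  expect_equal(z$p.value, 1)
  expect_equal(studentTTest(c(1, 1), c(1, 1))$p.value, 1)
  expect_error(studentTTest(c(1, 1), c(2, 2)), "degenerate")
  expect_error(studentTTest(1, c(1, 2)), "at least 2")
})

test_that("significance labels follow the conventional thresholds", {
  expect_identical(significanceLabel(0.05), "ns")
  expect_identical(significanceLabel(0.049), "*")
  expect_identical(significanceLabel(0.009), "**")
  expect_identical(significanceLabel(0.0009), "***")
  big <- studentTTest(c(1, 2, 3), c(101, 102, 103))
  expect_lt(big$p.value, 0.001)
  expect_identical(big$label, "***")
})

test_that("swapping groups negates t and preserves p exactly", {
  set.seed(81)
  a <- rnorm(5); b <- rnorm(7, 1)
  ab <- studentTTest(a, b); ba <- studentTTest(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_identical(ab$p.value, ba$p.value)
})

test_that("p decreases monotonically with the mean difference", {
  a <- c(-0.3, 0, 0.3)
  p <- vapply(seq(0.2, 3, by = 0.4), function(d) {
    studentTTest(a, a + d)$p.value
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("band areas are additive and baseline-corrected", {
  sp <- synthSpectrum(data.frame(center = 1600, width = 30, area = 2),
                      baseline = 0.1)
  full <- bandArea(sp, c(1400, 1800), baseline = "none")
  split <- bandArea(sp, c(1400, 1600), baseline = "none") +
           bandArea(sp, c(1600, 1800), baseline = "none")
  expect_equal(full, split, tolerance = 1e-9)
  ## a flat spectrum integrates to zero under the endpoint baseline
  flat <- data.frame(wavenumber = seq(4000, 600), signal = 0.25)
  expect_equal(bandArea(flat, c(1000, 2000), "linear_endpoints"), 0)
  expect_gt(bandArea(flat, c(1000, 2000), "none"), 0)
  expect_error(bandArea(flat, c(100, 300)), "outside")
})

test_that("band ratios report the four windows against the C-H reference", {
  peaks <- data.frame(center = c(3400, 1600, 1075, 2900),
                      width = c(40, 30, 20, 25),
                      area = c(2, 1, 1, 2))
  sp <- synthSpectrum(peaks)
  r <- bandRatios(sp, baseline = "none")
  expect_equal(r$a_d, 1, tolerance = 1e-2)
  expect_equal(r$b_d, 0.5, tolerance = 1e-2)
  expect_equal(r$c_d, 0.5, tolerance = 1e-2)
  short <- synthSpectrum(peaks, range = c(1300, 4000))
  expect_error(bandRatios(short), "window\\(s\\): c")
})

test_that("transmittance input converts to absorbance before integration", {
  wn <- seq(4000, 600)
  absb <- 0.02 + 0.5 * dnorm(wn, 1600, 30) * 30
  tr <- 10^(-absb)
  rA <- bandRatios(data.frame(wn, absb), input = "absorbance", baseline = "none")
  rT <- bandRatios(data.frame(wn, tr), input = "transmittance", baseline = "none")
  expect_equal(rT$b_d, rA$b_d, tolerance = 1e-9)
})

test_that("percent reduction inverts its own construction", {
  expect_equal(percentReduction(1.0, 0.808), 19.2, tolerance = 1e-9)
  expect_equal(percentReduction(1.0, 0.764), 23.6, tolerance = 1e-9)
  expect_equal(percentReduction(3.7, 3.7), 0)
  for (r in c(-60, -5, 0.5, 42, 99)) {
    expect_equal(percentReduction(2.5, 2.5 * (1 - r / 100)), r,
                 tolerance = 1e-9)
  }
  expect_error(percentReduction(0, 1), "positive")
})

test_that("diffusion barrier time follows the quadratic distance law", {
  expect_equal(diffusionT90(1, 1.03), 1)
  expect_equal(diffusionT90(10, 100), 1.03)
  for (k in c(2, 3, 7.5)) {
    expect_equal(diffusionT90(k * 4, 9), k^2 * diffusionT90(4, 9))
  }
  expect_error(diffusionT90(-1, 1), "positive")
  expect_error(diffusionT90(1, 0), "positive")
})
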