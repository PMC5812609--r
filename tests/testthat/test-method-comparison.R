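test_that("percent relative error follows its definition", {
  expect_equal(percentRelativeError(100, 100), 0)
  expect_equal(percentRelativeError(0.2335, 0.23), 1.521739, tolerance = 1e-6)
  expect_error(percentRelativeError(1, 0), "invalid truth")
})

test_that("accuracy summary reports exact order statistics", {
  s <- accuracySummary(c(1, 2, 3))
  expect_equal(s$median, 2); expect_equal(s$min, 1); expect_equal(s$max, 3)
  expect_equal(accuracySummary(5)$median, 5)
  # brute-force sort oracle on 14 pseudo-errors, even-count midpoint rule
  set.seed(3)
  e <- round(rnorm(14, 1.5, 3), 4)
  srt <- sort(e)
  expect_equal(accuracySummary(e)$median, (srt[7] + srt[8]) / 2)
  expect_equal(accuracySummary(e)$min, srt[1])
  expect_error(accuracySummary(numeric(0)), "no data")
})

test_that("Bland-Altman matches the hand-computed oracle", {
  # proportional differences of (102,98,104,96) vs 100:
  # 100*2/101, -100*2/99, 100*4/102, -100*4/98
  d <- c(200 / 101, -200 / 99, 400 / 102, -400 / 98)
  ba <- blandAltman(c(102, 98, 104, 96), rep(100, 4))
  expect_equal(ba@bias_pct, mean(d), tolerance = 1e-12)
  expect_equal(ba@sd_pct, sd(d), tolerance = 1e-12)
  expect_equal(ba@bias_pct, -0.0500, tolerance = 1e-3)
  expect_equal(ba@sd_pct, 3.6529, tolerance = 1e-4)
  expect_equal(ba@loa_low_pct, ba@bias_pct - 1.96 * ba@sd_pct)
  expect_equal(ba@loa_high_pct, ba@bias_pct + 1.96 * ba@sd_pct)
})

test_that("constant-ratio and identical series give closed-form results", {
  a <- c(1.8, 2.0, 2.2)
  ba <- blandAltman(1.02 * a, a)
  expect_equal(ba@bias_pct, 100 * 0.04 / 2.02, tolerance = 1e-9)  # 1.9802
  expect_equal(ba@sd_pct, 0, tolerance = 1e-12)
  ba0 <- blandAltman(a, a)
  expect_equal(ba0@bias_pct, 0)
  expect_equal(ba0@sd_pct, 0)
  expect_equal(c(ba0@loa_low_pct, ba0@loa_high_pct), c(0, 0))
})

test_that("swapping methods negates every proportional difference", {
  set.seed(11)
  for (i in 1:5) {
    a <- runif(8, 1.5, 2.5); b <- runif(8, 1.5, 2.5)
    ba_ab <- blandAltman(a, b); ba_ba <- blandAltman(b, a)
    expect_equal(ba_ab@bias_pct, -ba_ba@bias_pct, tolerance = 1e-12)
    expect_equal(ba_ab@sd_pct, ba_ba@sd_pct, tolerance = 1e-12)
    expect_equal(ibsa:::.ba_diffs(a, b, "proportional"),
                 -ibsa:::.ba_diffs(b, a, "proportional"), tolerance = 1e-12)
  }
})

test_that("Bland-Altman input validation", {
  expect_error(blandAltman(1, 1), "insufficient pairs")
  expect_error(blandAltman(c(1, -1), c(1, 1)), "invalid values")
  expect_equal(blandAltman(c(5, 7), c(4, 9), mode = "absolute")@bias_pct,
               mean(c(1, -2)))
})

test_that("bootstrap CIs are deterministic, degenerate on constant data, and contain the estimate", {
  a <- c(102, 98, 104, 96); b <- rep(100, 4)
  ci1 <- bootstrapCI(a, b, "bias", n_boot = 2000, seed = 1)
  ci2 <- bootstrapCI(a, b, "bias", n_boot = 2000, seed = 1)
  expect_identical(ci1, ci2)
  ba <- blandAltman(a, b)
  expect_lte(ci1[1], ba@bias_pct); expect_gte(ci1[2], ba@bias_pct)
  # constant-ratio pairs: sd identically 0 under any resampling
  v <- c(1.8, 2.0, 2.2, 2.4)
  ci_sd <- bootstrapCI(1.02 * v, v, "sd", n_boot = 500, seed = 2)
  expect_equal(unname(ci_sd), c(0, 0), tolerance = 1e-12)
})

test_that("bootstrap intervals shrink with sample size", {
  width <- function(n, seed) {
    set.seed(seed)
    v <- runif(n, 1.5, 2.5)
    a <- v * (1 + rnorm(n, 0, 0.02)); b <- v * (1 + rnorm(n, 0, 0.02))
    ci <- bootstrapCI(a, b, "bias", n_boot = 400, seed = seed)
    diff(ci)
  }
  shrunk <- sapply(1:20, function(s) width(200, s) < width(20, s + 1000))
  expect_gte(mean(shrunk), 0.95)
})

test_that("test-retest SD recovers the injected noise level", {
  # both replicates carry independent multiplicative noise s*, so the SD of
  # proportional differences estimates s* * sqrt(2)
  s_star <- 0.02
  set.seed(42)
  v <- runif(200, 1.4, 2.4)
  a <- v * (1 + rnorm(200, 0, s_star))
  b <- v * (1 + rnorm(200, 0, s_star))
  ba <- blandAltman(a, b)
  expect_lt(abs(ba@sd_pct - 100 * s_star * sqrt(2)) / (100 * s_star * sqrt(2)),
            0.15)
})

test_that("F/t comparison behaves on identical, scaled and degenerate series", {
  x <- c(1, 2, 3, 4)
  r <- compareMethods(x, x)
  expect_equal(r$f_statistic, 1)
  expect_equal(r$t_statistic, 0)
  r2 <- compareMethods(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(r2$f_statistic, 4)       # var ratio, larger variance on top
  set.seed(5)
  r3 <- compareMethods(rep(1, 50), 1 + rnorm(50))
  expect_lt(r3$f_pvalue, 0.05)
  expect_error(compareMethods(rep(1, 5), rep(2, 5)), "degenerate")
})
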