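test_that("the bundled capecitabine table loads and validates", {
  tab <- defaultBandTable()
  expect_equal(nrow(tab@bands), 8L)
  expect_equal(min(tab@bands$bsa_low), 1.2)
  expect_equal(max(tab@bands$bsa_high), 2.5)
  expect_true(all(diff(tab@bands$dose_mg) == 150))
})

test_that("malformed tables are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("bsa_low,bsa_high,dose_mg", "1.2,1.5,1000", "1.51,2.5,1150"), f)
  expect_error(loadBandTable(f), "non-contiguous bands")
  writeLines(c("bsa_low,bsa_high,dose_mg", "1.2,1.5,1300", "1.5,2.5,1150"), f)
  expect_error(loadBandTable(f), "invalid doses")
  writeLines(c("bsa_low,bsa_high,dose_mg", "1.2,2.5,1000"), f)
  expect_equal(nrow(loadBandTable(f)@bands), 1L)       # single band is valid
})

test_that("band assignment is half-open with clamping", {
  tab <- defaultBandTable()
  edges <- c(tab@bands$bsa_low, 2.5)
  expect_equal(assignBand(tab, edges[2]), 2L)      # interior boundary: upper band
  expect_equal(assignBand(tab, 0.9), 1L)           # below range clamps down
  expect_equal(assignBand(tab, 2.5), 8L)           # top edge clamps to last
  expect_equal(assignBand(tab, 3.0), 8L)
  # occupancy of a uniform grid is proportional to band widths
  grid <- seq(1.2, 2.5 - 1e-9, length.out = 1000)
  occ <- tabulate(assignBand(tab, grid), nbins = 8)
  widths <- tab@bands$bsa_high - tab@bands$bsa_low
  expect_true(all(abs(occ - 1000 * widths / 1.3) <= 1))
})

test_that("no error means no reclassification", {
  tab <- defaultBandTable()
  sim <- simulateReclassification(tab, sigma_pct = 0, n_samples = 1e4)
  expect_equal(sim@reclassification_rate, 0)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("bsa_low,bsa_high,dose_mg", "1.2,2.5,1000"), f)
  one <- loadBandTable(f)
  sim1 <- simulateReclassification(one, sigma_pct = 8, n_samples = 1e4)
  expect_equal(sim1@reclassification_rate, 0)      # clamping keeps band 1
})

test_that("simulation results are seed-reproducible and self-consistent", {
  tab <- defaultBandTable()
  s1 <- simulateReclassification(tab, n_samples = 5e4, seed = 7)
  s2 <- simulateReclassification(tab, n_samples = 5e4, seed = 7)
  expect_identical(s1@reclassification_rate, s2@reclassification_rate)
  expect_identical(s1@shift_histogram, s2@shift_histogram)
  expect_equal(sum(s1@shift_histogram), 1, tolerance = 1e-12)
  expect_equal(s1@reclassification_rate, 1 - s1@shift_histogram[["0"]])
  expect_equal(s1@mc_standard_error,
               sqrt(s1@reclassification_rate *
                      (1 - s1@reclassification_rate) / 5e4))
})

test_that("rate is non-decreasing in sigma under common random numbers", {
  tab <- defaultBandTable()
  rates <- sapply(1:5, function(s)
    simulateReclassification(tab, sigma_pct = s, n_samples = 5e4,
                             seed = 123)@reclassification_rate)
  expect_true(all(diff(rates) >= 0))
})

test_that("Monte Carlo agrees with the quadrature oracle on random tables", {
  set.seed(99)
  for (i in 1:5) {
    k <- sample(3:9, 1)
    edges <- sort(c(1.2, 2.5, runif(k - 1, 1.25, 2.45)))
    doses <- 1000 + 150 * (seq_len(k) - 1)
    tab <- new("DoseBandTable",
               bands = data.frame(bsa_low = edges[-(k + 1)],
                                  bsa_high = edges[-1], dose_mg = doses),
               name = sprintf("random%d", i))
    for (sg in c(2, 4.11, 8)) {
      sim <- simulateReclassification(tab, sigma_pct = sg, n_samples = 4e5,
                                      seed = 1000 + i)
      ana <- analyticReclassification(tab, sigma_pct = sg)
      expect_lt(abs(sim@reclassification_rate - ana),
                3 * sim@mc_standard_error + 1e-6)
    }
  }
  expect_equal(analyticReclassification(defaultBandTable(), 0), 0)
})

test_that("dose-step summary reflects the banding granularity", {
  s <- doseDeltaSummary(defaultBandTable())
  expect_equal(s$step_mg, 150)
  expect_equal(s$range_mg, 1050)
  expect_gt(s$step_over_range_pct, 10)
  two <- new("DoseBandTable",
             bands = data.frame(bsa_low = c(1.2, 1.8), bsa_high = c(1.8, 2.5),
                                dose_mg = c(1000, 1150)), name = "two")
  s2 <- doseDeltaSummary(two)
  expect_equal(s2$step_mg, 150); expect_equal(s2$range_mg, 150)
  expect_equal(s2$step_over_range_pct, 100)
  flat <- new("DoseBandTable",
              bands = data.frame(bsa_low = c(1.2, 1.8), bsa_high = c(1.8, 2.5),
                                 dose_mg = c(1000, 1000)), name = "flat")
  expect_error(doseDeltaSummary(flat), "no steps")
})
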