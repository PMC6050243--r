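test_that("IPIs are successive differences in milliseconds and conserve the span", {
  expect_equal(ipis(computeIPIs(PulseTrain(c(0, 0.010, 0.025)))), c(10, 15))

  tr <- PulseTrain(seq(0, 0.5, by = 0.050))
  expect_equal(ipis(computeIPIs(tr)), rep(50, 10))

  gen <- simulateSPI(speciesPreset("bimodal_burster", seed = 5)$config)
  s <- computeIPIs(gen)
  expect_length(ipis(s), nPulses(gen) - 1L)
  expect_equal(sum(ipis(s)),
               (max(pulseTimes(gen)) - min(pulseTimes(gen))) * 1000,
               tolerance = 1e-9)

  expect_error(computeIPIs(PulseTrain(0.5)), "at least 2")
})

test_that("histogram uses left-closed right-open uniform bins and normalises", {
  h <- ipiHistogram(IPISequence(c(10, 10, 20, 20)), binWidthMs = 10)
  # 10s fall in [10,20), 20s in [20,30)
  expect_equal(h@relFreq, c(0, 0.5, 0.5))
  expect_equal(h@binEdges, c(0, 10, 20, 30))
  expect_equal(sum(h@relFreq), 1)

  # boundary value goes into its own right-open bin
  h2 <- ipiHistogram(IPISequence(c(2, 3.9)), binWidthMs = 2)
  expect_equal(h2@relFreq, c(0, 1))

  hg <- ipiHistogram(computeIPIs(
    simulateSPI(renewal_config(seed = 2))), binWidthMs = 2)
  expect_equal(sum(hg@relFreq), 1, tolerance = 1e-12)

  expect_error(ipiHistogram(IPISequence(numeric())), "empty")
  expect_error(ipiHistogram(IPISequence(10), binWidthMs = 0), "> 0")
})

test_that("bimodal preset histograms peak within one bin of 14 and 23 ms", {
  for (seed in 1:3) {
    tr <- simulateSPI(speciesPreset("bimodal_burster", seed = seed)$config)
    h <- ipiHistogram(computeIPIs(tr), binWidthMs = 2)
    cen <- binCenters(h)
    top1 <- which.max(h@relFreq)
    # tallest separated peak: tallest bin not adjacent to the first
    away <- abs(seq_along(cen) - top1) > 1
    top2 <- which(away)[which.max(h@relFreq[away])]
    peaks <- sort(cen[c(top1, top2)])
    expect_lte(abs(peaks[1] - 14), 2)
    expect_lte(abs(peaks[2] - 23), 2)
  }
})

test_that("histogram averaging zero-pads, averages and propagates errors", {
  h1 <- ipiHistogram(IPISequence(c(10, 10, 20, 20)), binWidthMs = 10)
  avg <- averageHistograms(list(h1, h1))
  expect_equal(avg$histogram@relFreq, h1@relFreq)
  expect_equal(avg$std, rep(0, 3))

  h2 <- ipiHistogram(IPISequence(c(10, 20, 20, 20)), binWidthMs = 10)
  avg2 <- averageHistograms(list(h1, h2))
  expect_equal(avg2$histogram@relFreq, c(0, 0.375, 0.625))
  expect_equal(sum(avg2$histogram@relFreq), 1, tolerance = 1e-12)
  expect_equal(avg2$sem, avg2$std / sqrt(2))

  # shorter histograms are padded: averaging across different spans works
  h3 <- ipiHistogram(IPISequence(c(10, 45)), binWidthMs = 10)
  avg3 <- averageHistograms(list(h1, h3))
  expect_length(avg3$histogram@relFreq, 5)
  expect_equal(sum(avg3$histogram@relFreq), 1, tolerance = 1e-12)

  hb <- ipiHistogram(IPISequence(c(10, 20)), binWidthMs = 2)
  expect_error(averageHistograms(list(h1, hb)), "mixed bin widths")
  expect_error(averageHistograms(list(h1)), "at least 2")
})

test_that("run counting matches the definition and its oracle", {
  expect_equal(countRuns(IPISequence(c(5, 7, 9, 4, 4, 6))), 4)
  expect_equal(countRuns(IPISequence(c(10, 10, 10))), 1)
  expect_equal(countRuns(IPISequence(c(1, 2))), 1)
  expect_error(countRuns(IPISequence(5)), "at least 2")

  # tie tolerance turns near-equal pairs into 'equal'
  expect_equal(countRuns(IPISequence(c(10, 10.4, 20)), tieTolMs = 0.5), 2)
  expect_equal(countRuns(IPISequence(c(10, 10.4, 20)), tieTolMs = 0), 1)

  set.seed(42)
  for (i in 1:25) {
    x <- round(rgamma(sample(5:80, 1), 2, 0.05), sample(0:2, 1))
    x[x == 0] <- 0.5
    tol <- sample(c(0, 0.5), 1)
    expect_equal(countRuns(IPISequence(x), tieTolMs = tol),
                 runs_naive(x, tol))
  }
})

test_that("run count is shift-invariant, reversal-invariant and bounded", {
  set.seed(7)
  for (i in 1:10) {
    x <- rgamma(200, 2, 0.05)
    r <- countRuns(IPISequence(x))
    expect_equal(countRuns(IPISequence(x + 100)), r)
    expect_equal(countRuns(IPISequence(rev(x))), r)
    expect_gte(r, 1)
    expect_lte(r, length(x) - 1)
  }
})

test_that("iid sequences match the up-down runs expectation; correlated ones fall below", {
  # (2n - 1)/3 expectation for continuous iid data, checked by Monte Carlo
  set.seed(123)
  n <- 1000
  mean_runs <- mean(replicate(300, countRuns(IPISequence(runif(n)))))
  expect_lt(abs(mean_runs - (2 * n - 1) / 3) / ((2 * n - 1) / 3), 0.02)

  # positively correlated sequences produce fewer, longer runs; the effect
  # is strong for smooth AR(1) memory and directionally present (state
  # switches only) for the sticky two-state process
  ar <- mean(vapply(1:10, function(i) {
    countRuns(simulateIPIs(ar1_config(0.9, seed = 800 + i), n))
  }, 0))
  expect_lt(ar, 0.9 * (2 * n - 1) / 3)
  sticky <- mean(vapply(1:30, function(i) {
    countRuns(simulateIPIs(sticky_config(dwell = 25, seed = 900 + i), n))
  }, 0))
  expect_lt(sticky, (2 * n - 1) / 3)
})

test_that("feature extraction windows, bins and summarises correctly", {
  tr <- PulseTrain(c(0, 0.010, 0.020, 0.035))
  f <- extractFeatures(tr, windowLengthS = NULL)
  expect_equal(f@totalEods, 4L)
  expect_equal(f@rangeLowMs, 10)
  expect_equal(f@rangeHighMs, 15)
  expect_equal(f@nRuns, 2L)  # classes 0, + -> 2 runs

  # a constant train's mode is forced to the centre of its right-open bin:
  # exact 50-ms intervals fall in [50, 52), giving mode 51
  hm <- ipiHistogram(IPISequence(rep(50, 10)), binWidthMs = 2)
  expect_equal(binCenters(hm)[which.max(hm@relFreq)], 51)
  # same property through feature extraction, with intervals that are
  # binary-exact in seconds (62.5 ms) so no float noise crosses a bin edge
  const <- PulseTrain((0:10) * 0.0625)
  fc <- extractFeatures(const, windowLengthS = NULL)
  expect_equal(fc@modeIpiMs, 63)
  expect_equal(fc@rangeLowMs, 62.5)
  expect_equal(fc@rangeHighMs, 62.5)

  expect_error(extractFeatures(PulseTrain(c(0, 1), durationS = 120)),
               "degenerate window")
})

test_that("preset features are within a bin of the generator density mode", {
  tr <- simulateSPI(speciesPreset("broadband_slow", seed = 4)$config)
  f <- extractFeatures(tr)
  expect_gt(f@modeIpiMs, 40)
  h <- ipiHistogram(computeIPIs(extractWindow(tr, 0, 120)))
  expect_lte(abs(f@modeIpiMs - binCenters(h)[which.max(h@relFreq)]), 2)
})

test_that("featureTable lays out one labelled row per train", {
  trains <- simulateCohortTrains(3, "bimodal_burster", seed = 21)
  tab <- featureTable(trains)
  expect_equal(nrow(tab), 3)
  expect_named(tab, c("individual_id", "species_label", "sex", "phase",
                      "total_eods", "n_runs", "mode_ipi_ms",
                      "range_high_ms", "range_low_ms"))
  expect_true(all(tab$total_eods > 0))
  expect_true(all(tab$range_low_ms <= tab$mode_ipi_ms + 2 &
                  tab$mode_ipi_ms <= tab$range_high_ms + 2))
})
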