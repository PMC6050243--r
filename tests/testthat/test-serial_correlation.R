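test_that("serial correlation equals the naive double-loop oracle", {
  set.seed(11)
  for (i in 1:8) {
    N <- sample(50:500, 1)
    x <- rgamma(N, shape = 2, rate = 0.05)
    ml <- min(100L, N - 2L)
    expect_lt(max(abs(serialCorrelation(x, ml) - sc_naive(x, ml))), 1e-10)
  }
})

test_that("SC is exactly 1 at lag 0 and ~ -1/+1 for an alternating sequence", {
  x <- rep(c(10, 20), 100)
  sc <- serialCorrelation(x, 2)
  expect_identical(sc[1], 1)
  expect_equal(sc[2], -1, tolerance = 0.02)  # O(1/N) truncation
  expect_equal(sc[3], 1, tolerance = 0.02)

  expect_error(serialCorrelation(rep(10, 100), 5), "zero interval variance")
  expect_error(serialCorrelation(rgamma(10, 2), 20), "must exceed")
})

test_that("scrambling preserves the multiset and is deterministic per seed", {
  s <- IPISequence(c(10, 20, 30, 40, 50))
  a <- scrambleIPIs(s, seed = 7)
  b <- scrambleIPIs(s, seed = 7)
  c <- scrambleIPIs(s, seed = 8)
  expect_identical(ipis(a), ipis(b))
  expect_false(identical(ipis(a), ipis(c)))
  expect_equal(sort(ipis(a)), sort(ipis(s)))

  big <- simulateIPIs(sticky_config(dwell = 30, seed = 2), 2000)
  sc_big <- scrambleIPIs(big, seed = 1)
  expect_equal(sort(ipis(sc_big)), sort(ipis(big)))
  expect_error(scrambleIPIs(IPISequence(10), 1), "at least 2")
})

test_that("scrambling preserves every SPI feature except the run count", {
  tr <- simulateSPI(speciesPreset("bimodal_burster", seed = 13)$config)
  w <- extractWindow(tr, 0, 120)
  s <- computeIPIs(w)
  f0 <- extractFeatures(w, windowLengthS = NULL)
  scr <- scrambleIPIs(s, seed = 3)
  trs <- train_from_ipis_ms(ipis(scr))
  f1 <- extractFeatures(trs, windowLengthS = NULL)
  expect_equal(f1@totalEods, f0@totalEods)
  expect_equal(f1@modeIpiMs, f0@modeIpiMs)
  expect_equal(f1@rangeHighMs, f0@rangeHighMs)
  expect_equal(f1@rangeLowMs, f0@rangeLowMs)
})

test_that("permutation chance band is seed-deterministic and alpha-sensible", {
  s <- simulateIPIs(renewal_config(seed = 5), 500)
  b1 <- permutationChanceBand(s, 50, nPermutations = 50, seed = 9)
  b2 <- permutationChanceBand(s, 50, nPermutations = 50, seed = 9)
  expect_identical(b1, b2)
  expect_lt(b1$chanceLower, b1$chanceUpper)

  # alpha = 0.5 collapses the normal band onto the permutation mean ~ 0
  b3 <- permutationChanceBand(s, 50, nPermutations = 50, alpha = 0.5,
                              seed = 9)
  expect_lt(abs(b3$chanceUpper), 0.01)
  expect_equal(b3$chanceUpper, b3$chanceLower)

  expect_error(permutationChanceBand(s, 50, nPermutations = 1), "at least 2")
})

test_that("white-sequence chance level matches the asymptotic 1/sqrt(N) theory", {
  N <- 2000
  s <- simulateIPIs(renewal_config(seed = 17), N)
  b <- permutationChanceBand(s, 100, nPermutations = 100, alpha = 0.01,
                             seed = 1)
  expect_lt(abs(b$chanceUpper - qnorm(0.99) / sqrt(N)) /
              (qnorm(0.99) / sqrt(N)), 0.2)
})

test_that("percentile band is available and close to the normal band", {
  s <- simulateIPIs(renewal_config(seed = 23), 1000)
  bn <- permutationChanceBand(s, 50, nPermutations = 200, seed = 2)
  bp <- permutationChanceBand(s, 50, nPermutations = 200, seed = 2,
                              method = "percentile")
  expect_lt(abs(bn$chanceUpper - bp$chanceUpper), 0.02)
})

test_that("SC duration multiplies the first sub-chance lag by the median IPI", {
  s <- simulateIPIs(sticky_config(dwell = 15, seed = 3), 3000)
  cg <- serialCorrelogram(s, maxLag = 150, nPermutations = 100, seed = 4)
  d <- scDuration(cg)
  expect_equal(d$duration_ms,
               d$first_subthreshold_lag * median(ipis(s)))
  expect_false(d$censored)
  expect_gt(d$first_subthreshold_lag, 1)

  # a scrambled (renewal) sequence decorrelates at the first lag
  firsts <- vapply(1:20, function(i) {
    scr <- scrambleIPIs(s, seed = i)
    cgs <- serialCorrelogram(scr, maxLag = 50, nPermutations = 60,
                             seed = i + 100)
    cgs@firstSubthresholdLag
  }, 0L)
  expect_gte(mean(firsts == 1L), 0.9)
})

test_that("memory is detected: sticky SC_1 above chance, censoring flagged", {
  hits <- vapply(1:20, function(i) {
    s <- simulateIPIs(sticky_config(dwell = 25, seed = 400 + i), 3000)
    cg <- serialCorrelogram(s, maxLag = 50, nPermutations = 60, seed = i)
    scValues(cg)[2] > cg@chanceUpper
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  # very long dwell relative to the lag window censors the duration
  s <- simulateIPIs(sticky_config(dwell = 500, seed = 31), 2000)
  cg <- serialCorrelogram(s, maxLag = 20, nPermutations = 60, seed = 5)
  if (cg@censored) {
    expect_equal(scDuration(cg)$duration_ms, 20 * median(ipis(s)))
  }
  succeed()
})

test_that("correlogram averaging reduces to mean/SD/SEM per lag", {
  s1 <- simulateIPIs(renewal_config(seed = 41), 800)
  s2 <- simulateIPIs(renewal_config(seed = 42), 800)
  c1 <- serialCorrelogram(s1, maxLag = 30, nPermutations = 40, seed = 1)
  c2 <- serialCorrelogram(s2, maxLag = 30, nPermutations = 40, seed = 2)

  same <- averageCorrelograms(list(c1, c1))
  expect_equal(same$mean_sc, scValues(c1))
  expect_equal(same$std, rep(0, 31))

  both <- averageCorrelograms(list(c1, c2))
  expect_equal(both$mean_sc, (scValues(c1) + scValues(c2)) / 2)
  expect_equal(both$sem, both$std / sqrt(2))

  c3 <- serialCorrelogram(s1, maxLag = 10, nPermutations = 40, seed = 1)
  expect_error(averageCorrelograms(list(c1, c3)), "mismatched lag grids")
})

test_that("duration comparison wraps Kruskal-Wallis with group medians", {
  res <- compareDurations(c(1, 2, 3, 100, 101, 102),
                          rep(c("a", "b"), each = 3))
  expect_lt(res$p_value, 0.05)
  expect_equal(unname(res$medians), c(2, 101))

  same <- compareDurations(rep(c(5, 6, 7), 2), rep(c("a", "b"), each = 3))
  expect_gt(same$p_value, 0.9)

  expect_error(compareDurations(1:3, c("a", "a", "b")), "at least 2 values")
})

test_that("short-memory cohorts have shorter SC durations than long-memory ones", {
  dur <- function(dwell, seed) {
    s <- simulateIPIs(sticky_config(dwell = dwell, seed = seed), 3000)
    cg <- serialCorrelogram(s, maxLag = 200, nPermutations = 60, seed = seed)
    scDuration(cg)$duration_ms
  }
  short <- vapply(1:6, function(i) dur(8, 600 + i), 0)
  long <- vapply(1:6, function(i) dur(60, 700 + i), 0)
  expect_lt(median(short), median(long))
  res <- compareDurations(c(short, long), rep(c("short", "long"), each = 6))
  expect_lt(unname(res$medians["short"]), unname(res$medians["long"]))
})
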