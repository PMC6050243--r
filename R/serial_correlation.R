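#' Serial correlation of an IPI sequence
#'
#' The serial correlation at lag i is the mean lagged product of the
#' intervals, centred and normalised by the full-sequence statistics:
#' \deqn{SC_i = ( <IPI_k IPI_{k+i}>_{k=1..N-i} - <IPI>^2 ) / VAR(IPI)}
#' where the mean \code{<IPI>} and the (population) variance are taken over
#' the full sequence, so that \code{SC_0 = 1} exactly. Sustained SC above
#' chance indicates memory in the discharge sequence; a renewal process has
#' none.
#'
#' The lagged-product sums are computed via FFT (O(N log N) over all lags);
#' this is numerically identical to the direct sum.
#'
#' @param seq an [IPISequence-class] (or bare numeric vector of intervals)
#'   with length > maxLag + 1 and nonzero variance.
#' @param maxLag largest lag, >= 1.
#' @return Numeric vector of SC values for lags \code{0:maxLag}.
#' @seealso [serialCorrelogram()] for the full analysis with chance band.
#' @export
serialCorrelation <- function(seq, maxLag) {
  x <- if (is(seq, "IPISequence")) seq@intervals else as.numeric(seq)
  N <- length(x)
  maxLag <- as.integer(maxLag)
  if (maxLag < 1L) stop("maxLag must be >= 1")
  if (N <= maxLag + 1L) {
    stop(sprintf("sequence length (%d) must exceed maxLag + 1 (%d)",
                 N, maxLag + 1L))
  }
  m <- mean(x)
  v <- mean(x^2) - m^2
  if (v <= 0) {
    stop("degenerate sequence: zero interval variance, serial correlation undefined")
  }
  lag <- 0:maxLag
  (.laggedProductSums(x, maxLag) / (N - lag) - m^2) / v
}

# sum_{k=1..N-i} x_k x_{k+i} for i = 0..maxLag, via zero-padded FFT
# autocorrelation.
.laggedProductSums <- function(x, maxLag) {
  N <- length(x)
  n2 <- stats::nextn(2L * N, 2L)
  fx <- stats::fft(c(x, rep(0, n2 - N)))
  s <- Re(stats::fft(fx * Conj(fx), inverse = TRUE)) / n2
  s[1:(maxLag + 1L)]
}

#' Scramble an IPI sequence (renewal surrogate)
#'
#' Uniformly random permutation of the interval order. The IPI multiset --
#' and with it the sum, extremes and histogram -- is preserved exactly;
#' only the temporal order, and hence any serial correlation, is destroyed.
#' This is the surrogate used to realise the renewal null.
#'
#' @param seq an [IPISequence-class] with >= 2 intervals.
#' @param seed integer seed; the same seed yields the same permutation.
#' @return An [IPISequence-class] with permuted intervals.
#' @export
scrambleIPIs <- function(seq, seed) {
  stopifnot(is(seq, "IPISequence"))
  x <- seq@intervals
  if (length(x) < 2L) stop("need at least 2 intervals to scramble")
  perm <- withSeed(seed, sample.int(length(x)))
  IPISequence(x[perm], sourceId = paste0(seq@sourceId, "_scrambled"))
}

#' Permutation chance band for serial correlations
#'
#' Recomputes the serial correlation at lags 1..maxLag for
#' \code{nPermutations} random permutations of the interval sequence. Per
#' lag, the band is the permutation mean plus/minus the one-sided normal
#' quantile times the permutation SD (\code{method = "normal"}, default) or
#' the empirical \code{1 - alpha} / \code{alpha} quantiles
#' (\code{method = "percentile"}). The scalar \code{chanceUpper} /
#' \code{chanceLower} are these per-lag bounds averaged over all lags,
#' giving one horizontal threshold per recording.
#'
#' @param seq an [IPISequence-class] or numeric vector of intervals.
#' @param maxLag largest lag.
#' @param nPermutations number of permutations (>= 2; 250 by convention).
#' @param alpha one-sided type-I rate (0.01 by convention).
#' @param seed integer seed; bands are reproducible per seed.
#' @param method band construction, \code{"normal"} or \code{"percentile"}.
#' @return List with scalars \code{chanceUpper}, \code{chanceLower} and
#'   per-lag vectors \code{perLagUpper}, \code{perLagLower} (lags
#'   1..maxLag).
#' @export
permutationChanceBand <- function(seq, maxLag, nPermutations = 250,
                                  alpha = 0.01, seed = 1,
                                  method = c("normal", "percentile")) {
  method <- match.arg(method)
  x <- if (is(seq, "IPISequence")) seq@intervals else as.numeric(seq)
  nPermutations <- as.integer(nPermutations)
  if (nPermutations < 2L) stop("need at least 2 permutations")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  # permuted SCs at lags 1..maxLag, one row per permutation
  P <- withSeed(seed, {
    t(vapply(seq_len(nPermutations), function(p) {
      serialCorrelation(x[sample.int(length(x))], maxLag)[-1]
    }, numeric(maxLag)))
  })
  if (method == "normal") {
    z <- stats::qnorm(1 - alpha)
    mu <- colMeans(P)
    sdv <- apply(P, 2L, stats::sd)
    up <- mu + z * sdv
    lo <- mu - z * sdv
  } else {
    up <- apply(P, 2L, stats::quantile, probs = 1 - alpha, names = FALSE)
    lo <- apply(P, 2L, stats::quantile, probs = alpha, names = FALSE)
  }
  list(chanceUpper = mean(up), chanceLower = mean(lo),
       perLagUpper = up, perLagLower = lo)
}

#' Full serial-correlation analysis of an IPI sequence
#'
#' Computes the serial correlogram, its permutation chance band, the first
#' lag at which SC drops below the (upper) chance level, and the
#' serial-correlation duration: that lag multiplied by the median IPI of
#' the recording. If SC stays above the band through \code{maxLag} the
#' duration is censored at \code{maxLag} times the median IPI and flagged.
#'
#' @param seq an [IPISequence-class].
#' @param maxLag largest lag; default 150, capped at a quarter of the
#'   sequence length.
#' @param nPermutations,alpha,seed,method passed to
#'   [permutationChanceBand()].
#' @return A [SerialCorrelogram-class].
#' @examples
#' tr <- simulateSPI(speciesPreset("bimodal_burster")$config)
#' serialCorrelogram(computeIPIs(tr), seed = 1)
#' @export
serialCorrelogram <- function(seq, maxLag = NULL, nPermutations = 250,
                              alpha = 0.01, seed = 1,
                              method = c("normal", "percentile")) {
  stopifnot(is(seq, "IPISequence"))
  N <- length(seq@intervals)
  if (is.null(maxLag)) maxLag <- min(150L, floor(N / 4))
  maxLag <- as.integer(maxLag)
  sc <- serialCorrelation(seq, maxLag)
  band <- permutationChanceBand(seq, maxLag, nPermutations = nPermutations,
                                alpha = alpha, seed = seed, method = method)
  med <- stats::median(seq@intervals)
  sub <- which(sc[-1] < band$chanceUpper)   # lags 1..maxLag
  censored <- !length(sub)
  firstLag <- if (censored) maxLag else as.integer(sub[1])
  new("SerialCorrelogram",
      lags = 0:maxLag, sc = sc,
      chanceUpper = band$chanceUpper, chanceLower = band$chanceLower,
      perLagUpper = band$perLagUpper, perLagLower = band$perLagLower,
      nPermutations = as.integer(nPermutations), alpha = alpha,
      firstSubthresholdLag = firstLag, censored = censored,
      durationMs = firstLag * med, medianIpiMs = med,
      seed = as.integer(seed))
}

#' Serial-correlation duration of a correlogram
#'
#' The memory extent of a recording as a single time value: the first lag
#' at which SC falls below the upper chance level, multiplied by the median
#' IPI. Censored correlograms report \code{maxLag} times the median IPI
#' with \code{censored = TRUE}.
#'
#' @param correlogram a [SerialCorrelogram-class].
#' @param seq optional [IPISequence-class]; when given, the median IPI (and
#'   duration) are recomputed from it instead of the stored value.
#' @return List with \code{duration_ms}, \code{first_subthreshold_lag},
#'   \code{median_ipi_ms}, \code{censored}.
#' @export
scDuration <- function(correlogram, seq = NULL) {
  stopifnot(is(correlogram, "SerialCorrelogram"))
  med <- if (is.null(seq)) correlogram@medianIpiMs else {
    stats::median(if (is(seq, "IPISequence")) seq@intervals else seq)
  }
  list(duration_ms = correlogram@firstSubthresholdLag * med,
       first_subthreshold_lag = correlogram@firstSubthresholdLag,
       median_ipi_ms = med,
       censored = correlogram@censored)
}

#' Population average of serial correlograms
#'
#' Per-lag arithmetic mean with SD and SEM across individuals, as used for
#' the species-level correlogram displays.
#'
#' @param cgs list of at least two [SerialCorrelogram-class] objects on the
#'   same lag grid.
#' @return data.frame with columns lag, mean_sc, std, sem.
#' @export
averageCorrelograms <- function(cgs) {
  if (length(cgs) < 2L) stop("need at least 2 correlograms to average")
  stopifnot(all(vapply(cgs, is, TRUE, "SerialCorrelogram")))
  lags <- cgs[[1]]@lags
  same <- vapply(cgs, function(g) identical(g@lags, lags), TRUE)
  if (!all(same)) stop("correlograms have mismatched lag grids")
  mat <- vapply(cgs, scValues, numeric(length(lags)))
  std <- apply(mat, 1L, stats::sd)
  data.frame(lag = lags, mean_sc = rowMeans(mat), std = std,
             sem = std / sqrt(length(cgs)))
}

#' Compare serial-correlation durations between groups
#'
#' Non-parametric (Kruskal-Wallis) comparison of SC duration distributions,
#' e.g. between species or activity phases.
#'
#' @param durations numeric vector of SC durations (ms).
#' @param groups factor or character vector of group labels, same length.
#' @return List with \code{statistic} (Kruskal-Wallis H), \code{df},
#'   \code{p_value} and named \code{medians} per group.
#' @export
compareDurations <- function(durations, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 values")
  kw <- stats::kruskal.test(durations, groups)
  med <- tapply(durations, groups, stats::median)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value,
       medians = stats::setNames(as.numeric(med), names(med)))
}
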