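#' Compute the inter-pulse-interval sequence of a train
#'
#' \eqn{IPI_i = t_i - t_{i-1}}, converted from the train's seconds to
#' milliseconds. The sequence has one fewer element than the train has
#' pulses and its sum equals the span between first and last pulse.
#'
#' @param train a [PulseTrain-class] with at least 2 events.
#' @return An [IPISequence-class] in milliseconds.
#' @examples
#' ipis(computeIPIs(PulseTrain(c(0, 0.010, 0.025))))  # 10, 15
#' @export
computeIPIs <- function(train) {
  stopifnot(is(train, "PulseTrain"))
  if (nPulses(train) < 2L) {
    stop("at least 2 pulses are required to form intervals")
  }
  IPISequence(diff(train@timestamps) * 1000, sourceId = train@individualId)
}

#' Relative-frequency IPI histogram
#'
#' Bins the intervals into uniform left-closed right-open bins
#' \code{[0, w), [w, 2w), ...} spanning \code{[0, ceiling(max/w) * w)}.
#' The default width of 2 ms is used for all histogram-derived quantities
#' in the package, including the mode IPI feature.
#'
#' @param seq an [IPISequence-class], nonempty.
#' @param binWidthMs bin width in milliseconds (> 0).
#' @return An [IPIHistogram-class].
#' @export
ipiHistogram <- function(seq, binWidthMs = 2) {
  stopifnot(is(seq, "IPISequence"))
  x <- seq@intervals
  if (!length(x)) stop("cannot bin an empty interval sequence")
  if (binWidthMs <= 0) stop("bin width must be > 0")
  nbins <- max(1L, ceiling(max(x) / binWidthMs))
  # enlarge by one bin if max falls exactly on the last edge (right-open)
  if (max(x) >= nbins * binWidthMs) nbins <- nbins + 1L
  edges <- seq_len(nbins + 1L) * binWidthMs - binWidthMs
  idx <- findInterval(x, edges)          # edges[i] <= x < edges[i+1]
  counts <- tabulate(idx, nbins = nbins)
  new("IPIHistogram", binEdges = edges,
      relFreq = counts / length(x), nIntervals = length(x))
}

#' Bin centres of an IPI histogram
#' @param hist an [IPIHistogram-class].
#' @return Numeric vector of bin centres in ms.
#' @export
binCenters <- function(hist) {
  stopifnot(is(hist, "IPIHistogram"))
  e <- hist@binEdges
  (e[-length(e)] + e[-1]) / 2
}

#' Population average of IPI histograms
#'
#' Arithmetic mean of per-individual relative frequencies at a common bin
#' resolution, with per-bin standard deviation and standard error of the
#' mean. Histograms with a shorter span are zero-padded to the longest
#' span; bin widths must be identical.
#'
#' @param hists list of at least two [IPIHistogram-class] objects with the
#'   same bin width.
#' @return A list with \code{histogram} (the mean, as an
#'   [IPIHistogram-class]), and numeric vectors \code{std} and \code{sem}
#'   per bin.
#' @export
averageHistograms <- function(hists) {
  if (length(hists) < 2L) stop("need at least 2 histograms to average")
  stopifnot(all(vapply(hists, is, TRUE, "IPIHistogram")))
  widths <- vapply(hists, function(h) diff(h@binEdges[1:2]), 0)
  if (diff(range(widths)) > 1e-9 * widths[1]) {
    stop("histograms have mixed bin widths and cannot be averaged")
  }
  nb <- max(vapply(hists, function(h) length(h@relFreq), 0L))
  mat <- vapply(hists, function(h) {
    c(h@relFreq, rep(0, nb - length(h@relFreq)))
  }, numeric(nb))
  m <- rowMeans(mat)
  std <- apply(mat, 1L, stats::sd)
  avg <- new("IPIHistogram",
             binEdges = (0:nb) * widths[1], relFreq = m,
             nIntervals = sum(vapply(hists, function(h) h@nIntervals, 0L)))
  list(histogram = avg, std = std, sem = std / sqrt(length(hists)))
}

#' Count runs of increasing, decreasing or constant intervals
#'
#' Each adjacent pair of intervals is classified as positive, negative or
#' equal (differences within \code{tieTolMs} count as equal); a run is a
#' maximal streak of one class, as in the classical runs test. Under an iid
#' continuous interval sequence the expected run count for n intervals is
#' close to (2n - 1)/3; correlated (sticky) sequences produce fewer, longer
#' runs.
#'
#' @param seq an [IPISequence-class] with at least 2 intervals.
#' @param tieTolMs absolute tolerance (ms) below which a difference counts
#'   as "equal". Default 0: exact equality, which is detectable because
#'   acquisition quantises timestamps.
#' @return Integer run count (>= 1).
#' @examples
#' countRuns(IPISequence(c(5, 7, 9, 4, 4, 6)))  # classes + + - 0 + -> 4
#' @export
countRuns <- function(seq, tieTolMs = 0) {
  stopifnot(is(seq, "IPISequence"))
  x <- seq@intervals
  if (length(x) < 2L) stop("at least 2 intervals are required to count runs")
  d <- diff(x)
  cls <- ifelse(abs(d) <= tieTolMs, 0L, ifelse(d > 0, 1L, -1L))
  as.integer(1L + sum(cls[-1] != cls[-length(cls)]))
}

#' Extract the five SPI features from a pulse-train window
#'
#' Windows the train (default: first 120 s) and computes the five-variable
#' sequence summary: total EOD count, run count, mode IPI (centre of the
#' tallest bin of the 2-ms histogram -- continuous intervals have no
#' meaningful raw mode), and the longest and shortest interval.
#'
#' @param train a [PulseTrain-class].
#' @param windowStartS,windowLengthS analysis window in seconds. Use
#'   \code{windowLengthS = NULL} to take the train as-is (already windowed).
#' @param binWidthMs histogram bin width for the mode, ms.
#' @param tieTolMs tie tolerance for the run count, ms.
#' @return An [SPIFeatures-class].
#' @examples
#' tr <- simulateSPI(speciesPreset("bimodal_burster")$config)
#' extractFeatures(tr)
#' @export
extractFeatures <- function(train, windowStartS = 0, windowLengthS = 120,
                            binWidthMs = 2, tieTolMs = 0) {
  stopifnot(is(train, "PulseTrain"))
  w <- if (is.null(windowLengthS)) train else {
    extractWindow(train, windowStartS, windowLengthS)
  }
  if (nPulses(w) < 3L) {
    stop("degenerate window: need at least 3 events for feature extraction")
  }
  s <- computeIPIs(w)
  h <- ipiHistogram(s, binWidthMs = binWidthMs)
  mode_ipi <- binCenters(h)[which.max(h@relFreq)]
  new("SPIFeatures",
      totalEods = nPulses(w),
      nRuns = countRuns(s, tieTolMs = tieTolMs),
      modeIpiMs = mode_ipi,
      rangeHighMs = max(s@intervals),
      rangeLowMs = min(s@intervals),
      individualId = train@individualId, speciesLabel = train@speciesLabel,
      sex = train@sex, phase = train@phase)
}

#' Assemble a feature table from several trains
#'
#' One row per train, in the column layout used by the multivariate stage
#' and by the features CSV interface.
#'
#' @param trains list of [PulseTrain-class] objects.
#' @param ... passed on to [extractFeatures()].
#' @return data.frame with columns individual_id, species_label, sex, phase,
#'   total_eods, n_runs, mode_ipi_ms, range_high_ms, range_low_ms.
#' @export
featureTable <- function(trains, ...) {
  rows <- lapply(trains, function(tr) {
    f <- extractFeatures(tr, ...)
    data.frame(
      individual_id = f@individualId, species_label = f@speciesLabel,
      sex = f@sex, phase = f@phase,
      total_eods = f@totalEods, n_runs = f@nRuns,
      mode_ipi_ms = f@modeIpiMs, range_high_ms = f@rangeHighMs,
      range_low_ms = f@rangeLowMs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
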