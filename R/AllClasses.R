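#' @import methods
NULL

# Two events closer than the acquisition resolution (100 kHz -> 10 us) are
# treated as duplicates.
.TIME_RESOLUTION_S <- 1e-5

.VALID_SEX <- c("M", "F", "unknown")
.VALID_PHASE <- c("resting", "active", "synthetic")

#' PulseTrain: ordered electric-organ-discharge event times
#'
#' Holds the timestamps (seconds from recording start) of the electric organ
#' discharges (EODs) of one individual in one recording, together with
#' recording metadata. Timestamps must be strictly increasing; events closer
#' than 10 microseconds (the acquisition resolution) are rejected as
#' duplicates.
#'
#' @slot timestamps numeric, event times in seconds, strictly increasing,
#'   all within \code{[0, durationS]}.
#' @slot speciesLabel character(1), free-form species label.
#' @slot sex character(1), one of \code{"M"}, \code{"F"}, \code{"unknown"}.
#' @slot phase character(1), one of \code{"resting"}, \code{"active"},
#'   \code{"synthetic"}.
#' @slot individualId character(1), identifier of the recorded individual.
#' @slot durationS numeric(1), recording span in seconds.
#'
#' @seealso [PulseTrain()] for the constructor, [computeIPIs()],
#'   [extractWindow()], [readPulseTimes()].
#' @exportClass PulseTrain
setClass("PulseTrain",
  representation(
    timestamps = "numeric",
    speciesLabel = "character",
    sex = "character",
    phase = "character",
    individualId = "character",
    durationS = "numeric"
  )
)

setValidity("PulseTrain", function(object) {
  ts <- object@timestamps
  msgs <- character()
  if (length(object@durationS) != 1L || !is.finite(object@durationS) ||
      object@durationS < 0) {
    msgs <- c(msgs, "durationS must be a single non-negative finite number")
  }
  if (anyNA(ts)) msgs <- c(msgs, "timestamps contain NA")
  if (length(ts) && !length(msgs)) {
    if (any(ts < 0)) msgs <- c(msgs, "timestamps must be >= 0")
    if (any(ts > object@durationS + .TIME_RESOLUTION_S)) {
      msgs <- c(msgs, "timestamps exceed durationS")
    }
    d <- diff(ts)
    bad <- which(d < .TIME_RESOLUTION_S)
    if (length(bad)) {
      msgs <- c(msgs, sprintf(
        "timestamps must be strictly increasing (resolution %g s): row %d (t = %.6f) vs row %d (t = %.6f)",
        .TIME_RESOLUTION_S, bad[1] + 1L, ts[bad[1] + 1L], bad[1], ts[bad[1]]))
    }
  }
  for (f in c("speciesLabel", "individualId")) {
    if (length(slot(object, f)) != 1L) {
      msgs <- c(msgs, sprintf("%s must be a single string", f))
    }
  }
  if (length(object@sex) != 1L || !object@sex %in% .VALID_SEX) {
    msgs <- c(msgs, sprintf("sex must be one of %s",
                            paste(.VALID_SEX, collapse = ", ")))
  }
  if (length(object@phase) != 1L || !object@phase %in% .VALID_PHASE) {
    msgs <- c(msgs, sprintf("phase must be one of %s",
                            paste(.VALID_PHASE, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' IPISequence: ordered inter-pulse-intervals in milliseconds
#'
#' The sequence of inter-pulse-intervals (IPIs) derived from a
#' [PulseTrain-class]: \eqn{IPI_i = t_i - t_{i-1}}, reported in
#' milliseconds. Length is one less than the number of pulses and all
#' intervals are strictly positive.
#'
#' @slot intervals numeric, IPI values in milliseconds, all > 0.
#' @slot sourceId character(1), provenance string (usually the individual id).
#'
#' @seealso [computeIPIs()], [serialCorrelation()], [scrambleIPIs()].
#' @exportClass IPISequence
setClass("IPISequence",
  representation(intervals = "numeric", sourceId = "character")
)

setValidity("IPISequence", function(object) {
  x <- object@intervals
  msgs <- character()
  if (anyNA(x)) msgs <- c(msgs, "intervals contain NA")
  else if (length(x) && any(x <= 0)) {
    msgs <- c(msgs, "all intervals must be > 0")
  }
  if (length(object@sourceId) != 1L) {
    msgs <- c(msgs, "sourceId must be a single string")
  }
  if (length(msgs)) msgs else TRUE
})

#' IPIHistogram: relative-frequency histogram of inter-pulse-intervals
#'
#' Uniform-width, left-closed right-open bins starting at 0 ms. Bin width
#' defaults to 2 ms throughout the package.
#'
#' @slot binEdges numeric, bin edges in ms (length = number of bins + 1),
#'   uniform spacing.
#' @slot relFreq numeric, per-bin relative frequency, summing to 1.
#' @slot nIntervals integer(1), number of intervals binned.
#'
#' @seealso [ipiHistogram()], [averageHistograms()].
#' @exportClass IPIHistogram
setClass("IPIHistogram",
  representation(binEdges = "numeric", relFreq = "numeric",
                 nIntervals = "integer")
)

setValidity("IPIHistogram", function(object) {
  msgs <- character()
  e <- object@binEdges
  if (length(e) < 2L) msgs <- c(msgs, "need at least one bin")
  else {
    w <- diff(e)
    if (any(w <= 0) || diff(range(w)) > 1e-9 * w[1]) {
      msgs <- c(msgs, "bin width must be uniform and positive")
    }
    if (length(object@relFreq) != length(e) - 1L) {
      msgs <- c(msgs, "relFreq length must equal number of bins")
    }
  }
  if (object@nIntervals > 0L &&
      abs(sum(object@relFreq) - 1) > 1e-12) {
    msgs <- c(msgs, "relative frequencies must sum to 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' SPIFeatures: five-variable summary of a pulse-train window
#'
#' The five sequence-pulse-interval (SPI) features extracted from one
#' analysis window (120 s by default): the total number of EODs, the number
#' of runs of increasing/decreasing/constant IPIs, the mode IPI (centre of
#' the tallest 2-ms histogram bin), and the longest and shortest interval.
#'
#' @slot totalEods integer(1), events in the window.
#' @slot nRuns integer(1), run count of the IPI sequence.
#' @slot modeIpiMs numeric(1), ms, centre of the tallest histogram bin.
#' @slot rangeHighMs numeric(1), ms, longest interval.
#' @slot rangeLowMs numeric(1), ms, shortest interval.
#' @slot individualId,speciesLabel,sex,phase character(1), provenance.
#'
#' @seealso [extractFeatures()], [featureTable()].
#' @exportClass SPIFeatures
setClass("SPIFeatures",
  representation(
    totalEods = "integer", nRuns = "integer", modeIpiMs = "numeric",
    rangeHighMs = "numeric", rangeLowMs = "numeric",
    individualId = "character", speciesLabel = "character",
    sex = "character", phase = "character"
  )
)

setValidity("SPIFeatures", function(object) {
  msgs <- character()
  if (object@rangeLowMs > object@rangeHighMs) {
    msgs <- c(msgs, "rangeLowMs must not exceed rangeHighMs")
  }
  # the mode is a bin centre, so it can fall outside [rangeLow, rangeHigh]
  # by at most one bin width; the bin width is not stored, so only gross
  # violations are caught here
  if (object@modeIpiMs <= 0) {
    msgs <- c(msgs, "mode IPI must be positive")
  }
  if (object@totalEods >= 3L &&
      (object@nRuns < 1L || object@nRuns > object@totalEods - 2L)) {
    msgs <- c(msgs, "run count must be in [1, totalEods - 2]")
  }
  if (length(msgs)) msgs else TRUE
})

#' SerialCorrelogram: lagged serial correlation with permutation chance band
#'
#' Serial correlation (SC) of an IPI sequence per lag, the permutation-derived
#' chance band (scalar upper/lower thresholds averaged over lags), and the
#' serial-correlation duration: first sub-chance lag times the median IPI.
#'
#' @slot lags integer, 0..maxLag.
#' @slot sc numeric, serial correlation per lag; exactly 1 at lag 0.
#' @slot chanceUpper,chanceLower numeric(1), scalar chance thresholds.
#' @slot perLagUpper,perLagLower numeric, per-lag bounds (lags 1..maxLag).
#' @slot nPermutations integer(1), permutations used for the band.
#' @slot alpha numeric(1), one-sided type-I rate of the band.
#' @slot firstSubthresholdLag integer(1), smallest lag >= 1 with SC below
#'   \code{chanceUpper}; equals maxLag when censored.
#' @slot censored logical(1), TRUE when SC never dropped below the band.
#' @slot durationMs numeric(1), firstSubthresholdLag x median IPI.
#' @slot medianIpiMs numeric(1), median IPI of the source sequence, ms.
#' @slot seed integer(1), RNG seed used for the permutations.
#'
#' @seealso [serialCorrelogram()], [serialCorrelation()], [scDuration()].
#' @exportClass SerialCorrelogram
setClass("SerialCorrelogram",
  representation(
    lags = "integer", sc = "numeric",
    chanceUpper = "numeric", chanceLower = "numeric",
    perLagUpper = "numeric", perLagLower = "numeric",
    nPermutations = "integer", alpha = "numeric",
    firstSubthresholdLag = "integer", censored = "logical",
    durationMs = "numeric", medianIpiMs = "numeric", seed = "integer"
  )
)

setValidity("SerialCorrelogram", function(object) {
  msgs <- character()
  if (length(object@sc) != length(object@lags)) {
    msgs <- c(msgs, "sc and lags must have equal length")
  }
  if (length(object@sc) && abs(object@sc[1] - 1) > 1e-9) {
    msgs <- c(msgs, "SC at lag 0 must equal 1")
  }
  if (length(object@chanceUpper) == 1L && length(object@chanceLower) == 1L &&
      !is.na(object@chanceUpper) && object@chanceLower >= object@chanceUpper) {
    msgs <- c(msgs, "chanceLower must be below chanceUpper")
  }
  if (!object@censored && length(object@durationMs) == 1L &&
      is.finite(object@durationMs)) {
    expect <- object@firstSubthresholdLag * object@medianIpiMs
    if (abs(object@durationMs - expect) > 1e-6 * max(1, expect)) {
      msgs <- c(msgs, "durationMs must equal firstSubthresholdLag x medianIpiMs")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PreferenceSession: one focal fish in one two-choice playback condition
#'
#' Per-playback-interval occupancy times for the three centre zones of the
#' playback tank (B and D flank the two electrodes, C is neutral), together
#' with the physical side (A or E end) that carried stimulus 1 in each
#' interval. Zone times are mapped onto stimulus identity (side-unswapped)
#' before the strength of preference is computed.
#'
#' @slot focalId character(1), focal fish identifier.
#' @slot condition character(1), playback condition label (I..V).
#' @slot intervals data.frame with columns \code{interval_index},
#'   \code{side_of_stimulus1} (\code{"A"} or \code{"E"}), \code{t_zoneB_s},
#'   \code{t_zoneC_s}, \code{t_zoneD_s}.
#' @slot intervalLengthS numeric(1), playback interval length in seconds
#'   (default 120).
#'
#' @seealso [PreferenceSession()], [computeSOP()], [simulatePlaybackCohort()].
#' @exportClass PreferenceSession
setClass("PreferenceSession",
  representation(
    focalId = "character", condition = "character",
    intervals = "data.frame", intervalLengthS = "numeric"
  )
)

setValidity("PreferenceSession", function(object) {
  msgs <- character()
  need <- c("interval_index", "side_of_stimulus1",
            "t_zoneB_s", "t_zoneC_s", "t_zoneD_s")
  df <- object@intervals
  if (!all(need %in% names(df))) {
    msgs <- c(msgs, paste("intervals must have columns",
                          paste(need, collapse = ", ")))
  } else {
    tt <- df$t_zoneB_s + df$t_zoneC_s + df$t_zoneD_s
    if (any(df$t_zoneB_s < 0 | df$t_zoneC_s < 0 | df$t_zoneD_s < 0)) {
      msgs <- c(msgs, "zone times must be >= 0")
    }
    if (any(tt > object@intervalLengthS + 1e-6)) {
      msgs <- c(msgs, "zone times exceed the playback interval length")
    }
    if (!all(df$side_of_stimulus1 %in% c("A", "E"))) {
      msgs <- c(msgs, "side_of_stimulus1 must be 'A' or 'E'")
    }
  }
  if (length(msgs)) msgs else TRUE
})
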