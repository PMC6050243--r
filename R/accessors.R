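#' Construct a PulseTrain
#'
#' @param timestamps numeric vector of event times in seconds, strictly
#'   increasing.
#' @param speciesLabel,individualId free-form identifier strings.
#' @param sex one of \code{"M"}, \code{"F"}, \code{"unknown"}.
#' @param phase one of \code{"resting"}, \code{"active"}, \code{"synthetic"}.
#' @param durationS recording span in seconds; defaults to the last event
#'   time.
#' @return A [PulseTrain-class] object.
#' @examples
#' tr <- PulseTrain(c(0, 0.010, 0.025), individualId = "fish1")
#' nPulses(tr)
#' @export
PulseTrain <- function(timestamps, speciesLabel = "unknown",
                       sex = "unknown", phase = "resting",
                       individualId = "unknown", durationS = NULL) {
  timestamps <- as.numeric(timestamps)
  if (is.null(durationS)) {
    durationS <- if (length(timestamps)) max(timestamps) else 0
  }
  new("PulseTrain", timestamps = timestamps,
      speciesLabel = as.character(speciesLabel), sex = as.character(sex),
      phase = as.character(phase), individualId = as.character(individualId),
      durationS = as.numeric(durationS))
}

#' Construct an IPISequence
#'
#' @param intervals numeric vector of inter-pulse-intervals in milliseconds,
#'   all > 0.
#' @param sourceId provenance string.
#' @return An [IPISequence-class] object.
#' @export
IPISequence <- function(intervals, sourceId = "unknown") {
  new("IPISequence", intervals = as.numeric(intervals),
      sourceId = as.character(sourceId))
}

#' Construct a PreferenceSession
#'
#' @param focalId focal fish identifier.
#' @param condition playback condition label (the study design uses I..V).
#' @param intervals data.frame with columns \code{interval_index},
#'   \code{side_of_stimulus1}, \code{t_zoneB_s}, \code{t_zoneC_s},
#'   \code{t_zoneD_s}.
#' @param intervalLengthS length of one playback interval in seconds.
#' @return A [PreferenceSession-class] object.
#' @export
PreferenceSession <- function(focalId, condition, intervals,
                              intervalLengthS = 120) {
  new("PreferenceSession", focalId = as.character(focalId),
      condition = as.character(condition),
      intervals = as.data.frame(intervals),
      intervalLengthS = as.numeric(intervalLengthS))
}

#' @describeIn PulseTrain-class Event times in seconds.
#' @param object,x a package object.
#' @export
setGeneric("pulseTimes", function(x) standardGeneric("pulseTimes"))

#' @rdname PulseTrain-class
#' @export
setMethod("pulseTimes", "PulseTrain", function(x) x@timestamps)

#' @describeIn PulseTrain-class Number of pulses (EODs).
#' @export
setGeneric("nPulses", function(x) standardGeneric("nPulses"))

#' @rdname PulseTrain-class
#' @export
setMethod("nPulses", "PulseTrain", function(x) length(x@timestamps))

#' @describeIn PulseTrain-class Recording span in seconds.
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))

#' @rdname PulseTrain-class
#' @export
setMethod("durationS", "PulseTrain", function(x) x@durationS)

#' @describeIn PulseTrain-class Species label.
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))

#' @rdname PulseTrain-class
#' @export
setMethod("speciesLabel", "PulseTrain", function(x) x@speciesLabel)

#' @describeIn PulseTrain-class Individual identifier.
#' @export
setGeneric("individualId", function(x) standardGeneric("individualId"))

#' @rdname PulseTrain-class
#' @export
setMethod("individualId", "PulseTrain", function(x) x@individualId)

#' @describeIn IPISequence-class Interval values in milliseconds.
#' @export
setGeneric("ipis", function(x) standardGeneric("ipis"))

#' @rdname IPISequence-class
#' @param x an [IPISequence-class].
#' @export
setMethod("ipis", "IPISequence", function(x) x@intervals)

#' @rdname IPISequence-class
#' @export
setMethod("length", "IPISequence", function(x) length(x@intervals))

#' @describeIn SerialCorrelogram-class Serial correlation values, one per
#'   lag starting at lag 0.
#' @export
setGeneric("scValues", function(x) standardGeneric("scValues"))

#' @rdname SerialCorrelogram-class
#' @param x a [SerialCorrelogram-class].
#' @export
setMethod("scValues", "SerialCorrelogram", function(x) x@sc)

#' @describeIn SerialCorrelogram-class Scalar chance band as
#'   \code{c(lower, upper)}.
#' @export
setGeneric("chanceBand", function(x) standardGeneric("chanceBand"))

#' @rdname SerialCorrelogram-class
#' @export
setMethod("chanceBand", "SerialCorrelogram",
          function(x) c(lower = x@chanceLower, upper = x@chanceUpper))

setMethod("show", "PulseTrain", function(object) {
  cat(sprintf(
    "PulseTrain: %d events over %.3f s (%s, %s, %s, id=%s)\n",
    length(object@timestamps), object@durationS, object@speciesLabel,
    object@sex, object@phase, object@individualId))
})

setMethod("show", "IPISequence", function(object) {
  x <- object@intervals
  cat(sprintf("IPISequence [%s]: %d intervals", object@sourceId, length(x)))
  if (length(x)) {
    cat(sprintf(", median %.1f ms, range [%.1f, %.1f] ms",
                stats::median(x), min(x), max(x)))
  }
  cat("\n")
})

setMethod("show", "IPIHistogram", function(object) {
  cat(sprintf(
    "IPIHistogram: %d bins of %.3g ms over [0, %.3g) ms, n = %d intervals\n",
    length(object@relFreq), diff(object@binEdges[1:2]),
    max(object@binEdges), object@nIntervals))
})

setMethod("show", "SPIFeatures", function(object) {
  cat(sprintf(
    paste0("SPIFeatures [%s, %s, %s, %s]\n",
           "  total EODs: %d | runs: %d | mode IPI: %.1f ms | ",
           "range: [%.1f, %.1f] ms\n"),
    object@individualId, object@speciesLabel, object@sex, object@phase,
    object@totalEods, object@nRuns, object@modeIpiMs,
    object@rangeLowMs, object@rangeHighMs))
})

setMethod("show", "SerialCorrelogram", function(object) {
  cat(sprintf(
    paste0("SerialCorrelogram: lags 0..%d, chance band [%.4f, %.4f] ",
           "(%d permutations, alpha %.3g)\n"),
    max(object@lags), object@chanceLower, object@chanceUpper,
    object@nPermutations, object@alpha))
  cat(sprintf("  first sub-chance lag: %d%s | median IPI %.2f ms | SC duration %.1f ms\n",
    object@firstSubthresholdLag,
    if (object@censored) " (censored)" else "",
    object@medianIpiMs, object@durationMs))
})

setMethod("show", "PreferenceSession", function(object) {
  cat(sprintf(
    "PreferenceSession: focal %s, condition %s, %d intervals of %.0f s\n",
    object@focalId, object@condition, nrow(object@intervals),
    object@intervalLengthS))
})
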