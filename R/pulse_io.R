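#' Read a pulse-timestamp train from a text file
#'
#' Pulse trains are plain text: one numeric timestamp (seconds from
#' recording start) per row. Lines beginning with \code{#} are metadata
#' headers of the form \code{# key=value}; recognised keys are
#' \code{species_label}, \code{sex}, \code{phase}, \code{individual_id} and
#' \code{duration_s}. Explicit \code{metadata} arguments override header
#' values.
#'
#' @param path path to the timestamp file.
#' @param metadata named list of metadata overrides (same keys as above).
#' @return A validated [PulseTrain-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("# individual_id=f1", "0.000", "0.010", "0.025"), f)
#' readPulseTimes(f)
#' @export
readPulseTimes <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty pulse-train file: ", path)

  hdr <- grepl("^\\s*#", lines)
  meta <- list()
  for (h in sub("^\\s*#\\s*", "", lines[hdr])) {
    kv <- strsplit(h, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  meta[names(metadata)] <- metadata

  body <- lines[!hdr]
  if (!length(body)) stop("no timestamps in file: ", path)
  ts <- suppressWarnings(as.numeric(body))
  if (anyNA(ts)) {
    stop("non-numeric timestamp at data row ", which(is.na(ts))[1],
         ": '", body[which(is.na(ts))[1]], "'")
  }
  d <- diff(ts)
  bad <- which(d < .TIME_RESOLUTION_S)
  if (length(bad)) {
    stop(sprintf(
      "timestamps not strictly increasing: data row %d (t = %.6f) after row %d (t = %.6f)",
      bad[1] + 1L, ts[bad[1] + 1L], bad[1], ts[bad[1]]))
  }
  dur <- if (!is.null(meta$duration_s)) as.numeric(meta$duration_s) else max(ts)
  PulseTrain(ts,
    speciesLabel = meta$species_label %||% "unknown",
    sex = meta$sex %||% "unknown",
    phase = meta$phase %||% "resting",
    individualId = meta$individual_id %||% "unknown",
    durationS = dur)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pulse train to a text file
#'
#' Writes \code{# key=value} metadata headers followed by one timestamp per
#' row at microsecond precision, so that
#' \code{readPulseTimes(writePulseTimes(x))} reproduces the timestamps to at
#' least 1e-6 s and repeated writes are byte-identical.
#'
#' @param train a [PulseTrain-class].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writePulseTimes <- function(train, path) {
  stopifnot(is(train, "PulseTrain"))
  if (!is.character(path) || length(path) != 1L || !nzchar(path)) {
    stop("path must be a single non-empty file path")
  }
  hdr <- c(
    sprintf("# species_label=%s", train@speciesLabel),
    sprintf("# sex=%s", train@sex),
    sprintf("# phase=%s", train@phase),
    sprintf("# individual_id=%s", train@individualId),
    sprintf("# duration_s=%.6f", train@durationS))
  con <- file(path, open = "wb")  # binary mode: byte-stable line endings
  on.exit(close(con))
  writeLines(c(hdr, sprintf("%.6f", train@timestamps)), con, sep = "\n")
  invisible(path)
}

#' Extract a time window from a pulse train
#'
#' Selects the events with \code{start_s <= t < start_s + length_s}
#' (half-open, so adjacent windows never share an event) and re-zeroes their
#' times to the window start. Analyses in this package conventionally use
#' the first 120 s of a recording; the window start is exposed because which
#' excerpt of a long recording to analyse is a study choice, not a constant.
#'
#' @param train a [PulseTrain-class].
#' @param startS window start in seconds (>= 0).
#' @param lengthS window length in seconds; the window must lie within the
#'   recording span.
#' @return A [PulseTrain-class] with the selected, re-zeroed events and
#'   \code{durationS = lengthS}.
#' @examples
#' tr <- PulseTrain(c(1, 5, 9, 13), durationS = 14)
#' pulseTimes(extractWindow(tr, 4, 6))  # 1 and 5 (re-zeroed from 5 and 9)
#' @export
extractWindow <- function(train, startS, lengthS) {
  stopifnot(is(train, "PulseTrain"))
  if (startS < 0) stop("window start must be >= 0")
  if (lengthS <= 0) stop("window length must be > 0")
  if (startS + lengthS > train@durationS + .TIME_RESOLUTION_S) {
    stop(sprintf("window [%g, %g) extends beyond the recording span %g s",
                 startS, startS + lengthS, train@durationS))
  }
  ts <- train@timestamps
  keep <- ts >= startS & ts < startS + lengthS
  PulseTrain(ts[keep] - startS,
    speciesLabel = train@speciesLabel, sex = train@sex,
    phase = train@phase, individualId = train@individualId,
    durationS = lengthS)
}
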