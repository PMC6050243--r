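#' Synthetic pulse-train generator configuration
#'
#' Describes an interval-generating process for [simulateSPI()]. Three
#' processes are available:
#' \describe{
#'   \item{renewal}{each interval is an independent draw from the mixture;
#'     no memory.}
#'   \item{sticky_state}{a semi-Markov burst/pause mechanism: a hidden
#'     state picks the mixture component; at each interval the state is
#'     redrawn from the component weights with probability 1/dwell and kept
#'     otherwise, so runs of like intervals with expected length ~dwell
#'     produce serial correlation decaying as (1 - 1/dwell)^lag.}
#'   \item{ar1_log}{log-intervals follow a stationary AR(1) with
#'     coefficient phi; the marginal interval distribution is the (single,
#'     lognormal) component regardless of phi, so memory strength can be
#'     varied with the interval distribution held fixed.}
#' }
#' Components are parameterised by their mean (\code{location_ms}) and SD
#' (\code{scale_ms}) in milliseconds, for either a gamma or a lognormal
#' family.
#'
#' @param process one of \code{"renewal"}, \code{"sticky_state"},
#'   \code{"ar1_log"}.
#' @param components data.frame with columns \code{weight},
#'   \code{location_ms}, \code{scale_ms}, \code{family} (\code{"gamma"} or
#'   \code{"lognormal"}); weights must sum to 1.
#' @param dwell expected intervals per state (sticky_state only), > 1.
#' @param phi AR(1) coefficient in [0, 1) (ar1_log only).
#' @param duration_s simulated recording span in seconds.
#' @param seed integer seed; simulation is deterministic per seed.
#' @return A validated config list of class \code{"spiConfig"}.
#' @seealso [speciesPreset()] for calibrated configs, [simulateSPI()].
#' @export
spiConfig <- function(process = c("renewal", "sticky_state", "ar1_log"),
                      components, dwell = NULL, phi = NULL,
                      duration_s = 120, seed = 1) {
  process <- match.arg(process)
  components <- as.data.frame(components)
  need <- c("weight", "location_ms", "scale_ms", "family")
  if (!all(need %in% names(components))) {
    stop("components needs columns ", paste(need, collapse = ", "))
  }
  if (abs(sum(components$weight) - 1) > 1e-9) {
    stop("mixture weights must sum to 1")
  }
  if (any(components$weight < 0) || any(components$location_ms <= 0) ||
      any(components$scale_ms <= 0)) {
    stop("weights must be >= 0 and location/scale parameters > 0")
  }
  if (!all(components$family %in% c("gamma", "lognormal"))) {
    stop("family must be 'gamma' or 'lognormal'")
  }
  if (process == "sticky_state") {
    if (is.null(dwell) || dwell <= 1) stop("sticky_state needs dwell > 1")
  } else if (process == "ar1_log") {
    if (is.null(phi) || phi < 0 || phi >= 1) {
      stop("ar1_log needs phi in [0, 1)")
    }
    if (nrow(components) != 1L || components$family[1] != "lognormal") {
      stop("ar1_log uses a single lognormal component")
    }
    dwell <- NULL
  } else {
    if (!is.null(dwell) || !is.null(phi)) {
      stop("renewal process takes no memory parameters")
    }
  }
  structure(list(process = process, components = components,
                 dwell = dwell, phi = phi,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "spiConfig")
}

# lognormal meanlog/sdlog matching a given mean and SD in ms
.lnormPars <- function(location, scale) {
  sdlog2 <- log(1 + (scale / location)^2)
  list(meanlog = log(location) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# draw n intervals from one mixture component, using the active RNG stream
.drawComponent <- function(comp, n) {
  if (n == 0L) return(numeric())
  if (comp$family == "gamma") {
    shape <- (comp$location_ms / comp$scale_ms)^2
    stats::rgamma(n, shape = shape, rate = shape / comp$location_ms)
  } else {
    p <- .lnormPars(comp$location_ms, comp$scale_ms)
    stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
  }
}

# draw n intervals under the configured process; caller owns the RNG state
.drawIntervals <- function(config, n) {
  comps <- config$components
  if (config$process == "ar1_log") {
    p <- .lnormPars(comps$location_ms[1], comps$scale_ms[1])
    phi <- config$phi
    e <- c(stats::rnorm(1, 0, p$sdlog),
           stats::rnorm(n - 1, 0, p$sdlog * sqrt(1 - phi^2)))
    x <- as.numeric(stats::filter(e, phi, method = "recursive"))
    return(exp(p$meanlog + x))
  }
  state <- if (config$process == "renewal") {
    sample.int(nrow(comps), n, replace = TRUE, prob = comps$weight)
  } else {
    # resample the hidden state with prob 1/dwell, keep it otherwise
    res <- stats::runif(n) < 1 / config$dwell
    res[1] <- TRUE
    draws <- sample.int(nrow(comps), sum(res), replace = TRUE,
                        prob = comps$weight)
    idx <- cumsum(res)
    draws[idx]
  }
  out <- numeric(n)
  for (j in seq_len(nrow(comps))) {
    sel <- state == j
    out[sel] <- .drawComponent(comps[j, ], sum(sel))
  }
  out
}

#' Simulate a synthetic pulse train
#'
#' Draws inter-pulse-intervals under the configured process until the
#' cumulative time exceeds the configured duration, places the first pulse
#' at t = 0 and truncates at \code{duration_s} (so the last timestamp is
#' within the span and the next drawn interval would exceed it).
#'
#' @param config an [spiConfig()] (or a [speciesPreset()]'s \code{$config}).
#' @param individualId,speciesLabel metadata for the returned train.
#' @return A [PulseTrain-class] with \code{phase = "synthetic"}.
#' @examples
#' tr <- simulateSPI(speciesPreset("bimodal_burster")$config)
#' nPulses(tr)
#' @export
simulateSPI <- function(config, individualId = "sim",
                        speciesLabel = NULL) {
  stopifnot(inherits(config, "spiConfig"))
  target_ms <- config$duration_s * 1000
  mean_ipi <- sum(config$components$weight * config$components$location_ms)
  ts_ms <- withSeed(config$seed, {
    n <- ceiling(target_ms / mean_ipi * 1.25) + 50L
    repeat {
      x <- .drawIntervals(config, n)
      if (sum(x) >= target_ms) break
      n <- 2L * n
    }
    cs <- c(0, cumsum(x))
    cs[cs <= target_ms]
  })
  PulseTrain(ts_ms / 1000,
    speciesLabel = speciesLabel %||% config$process,
    sex = "unknown", phase = "synthetic",
    individualId = individualId, durationS = config$duration_s)
}

#' Simulate a fixed-length IPI sequence
#'
#' Direct interval-sequence counterpart of [simulateSPI()] for analyses
#' that are parameterised by the number of intervals rather than by
#' recording time (e.g. serial-correlation calibration studies).
#'
#' @param config an [spiConfig()].
#' @param n number of intervals to draw.
#' @return An [IPISequence-class] of length \code{n}.
#' @export
simulateIPIs <- function(config, n) {
  stopifnot(inherits(config, "spiConfig"))
  x <- withSeed(config$seed, .drawIntervals(config, as.integer(n)))
  IPISequence(x, sourceId = paste0("sim_", config$process))
}

#' Calibrated species presets
#'
#' Two generator presets emulating the interval statistics of the study
#' species during the resting phase:
#' \describe{
#'   \item{bimodal_burster}{burst-and-pause discharger: sharp interval
#'     modes at 14 and 23 ms plus a long-interval pause state, ~3150 events
#'     per 120 s, short memory (state dwell 8 intervals). The 2-ms IPI
#'     histogram is bimodal with its two tallest separated peaks at the
#'     configured modes.}
#'   \item{broadband_slow}{slow, heterogeneous discharger: intervals spread
#'     over ~25-150 ms with no sharp mode, ~1300 events per 120 s, long
#'     memory (state dwell 40 intervals).}
#' }
#'
#' @param name \code{"bimodal_burster"} or \code{"broadband_slow"}.
#' @param duration_s,seed forwarded into the config.
#' @return List with \code{name} and \code{config} (an [spiConfig()]).
#' @export
speciesPreset <- function(name = c("bimodal_burster", "broadband_slow"),
                          duration_s = 120, seed = 1) {
  name <- match.arg(name)
  config <- if (name == "bimodal_burster") {
    spiConfig("sticky_state",
      components = data.frame(
        weight = c(0.45, 0.40, 0.15),
        location_ms = c(14.30, 23.50, 148),
        scale_ms = c(1.72, 2.82, 88.8),
        family = "lognormal"),
      dwell = 8, duration_s = duration_s, seed = seed)
  } else {
    spiConfig("sticky_state",
      components = data.frame(
        weight = c(0.15, 0.30, 0.30, 0.25),
        location_ms = c(50, 75, 105, 140),
        scale_ms = c(12, 19, 26, 35),
        family = "lognormal"),
      dwell = 40, duration_s = duration_s, seed = seed)
  }
  list(name = name, config = config)
}

#' Simulate a cohort of preset pulse trains
#'
#' Generates \code{n} independent trains from a species preset, with
#' per-train seeds derived deterministically from \code{seed}.
#'
#' @param n number of individuals.
#' @param preset preset name, see [speciesPreset()].
#' @param duration_s recording span per train, seconds.
#' @param seed integer master seed.
#' @return List of [PulseTrain-class] objects with ids
#'   \code{<preset>_01} ...
#' @export
simulateCohortTrains <- function(n, preset = "bimodal_burster",
                                 duration_s = 120, seed = 1) {
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i) {
    ps <- speciesPreset(preset, duration_s = duration_s, seed = seeds[i])
    simulateSPI(ps$config,
                individualId = sprintf("%s_%02d", preset, i),
                speciesLabel = preset)
  })
}

#' Simulate a two-choice playback cohort
#'
#' Generates one [PreferenceSession-class] per fish: 8 playback intervals
#' of 120 s by default, with the physical side of stimulus 1 balanced and
#' randomised across intervals. Each fish's latent preference is the
#' cohort preference theta perturbed on the Fisher-z (atanh) scale by
#' normal noise of SD \code{noiseSd}, which keeps preferences in [-1, 1]
#' and makes the boundaries exact: theta = 1 yields zero time at the
#' non-preferred stimulus for every fish. Zone times split the fish's
#' active (non-neutral) time in proportion (1 + theta)/2 vs (1 - theta)/2,
#' so the expected session SOP equals the fish's latent preference.
#'
#' @param nFish cohort size (>= 1).
#' @param truePreference cohort-level preference theta in [-1, 1].
#' @param noiseSd between-fish SD on the atanh scale (~= SOP scale for
#'   moderate theta).
#' @param seed integer seed.
#' @param nIntervals playback intervals per session.
#' @param intervalLengthS interval length, seconds.
#' @param condition condition label attached to the sessions.
#' @return List of [PreferenceSession-class] objects.
#' @examples
#' sess <- simulatePlaybackCohort(12, 0.4, seed = 1)
#' mean(sapply(sess, function(s) computeSOP(s)$sop))
#' @export
simulatePlaybackCohort <- function(nFish, truePreference, noiseSd = 0.3,
                                   seed = 1, nIntervals = 8,
                                   intervalLengthS = 120,
                                   condition = "I") {
  if (abs(truePreference) > 1) stop("truePreference must lie in [-1, 1]")
  if (nFish < 1L) stop("nFish must be >= 1")
  withSeed(seed, {
    lapply(seq_len(nFish), function(f) {
      theta <- tanh(atanh(truePreference) + stats::rnorm(1, 0, noiseSd))
      half <- nIntervals %/% 2L
      sides <- sample(c(rep(c("A", "E"), half),
                        if (nIntervals %% 2L) sample(c("A", "E"), 1L)))
      active <- stats::runif(nIntervals, 0.3, 0.8) * intervalLengthS
      tStim <- active * (1 + theta) / 2   # time with stimulus 1
      tOther <- active - tStim
      swap <- sides == "E"
      df <- data.frame(
        interval_index = seq_len(nIntervals),
        side_of_stimulus1 = sides,
        t_zoneB_s = ifelse(swap, tOther, tStim),
        t_zoneC_s = intervalLengthS - active,
        t_zoneD_s = ifelse(swap, tStim, tOther))
      PreferenceSession(sprintf("fish_%02d", f), condition, df,
                        intervalLengthS = intervalLengthS)
    })
  })
}
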