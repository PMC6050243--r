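#' Strength of preference of one playback session
#'
#' Sums the zone times over the playback intervals after side-unswapping:
#' in intervals where stimulus 1 played from the E end, zones B and D are
#' exchanged so that zone B always counts time spent with stimulus 1. The
#' strength of preference is then \deqn{SOP = (t_B - t_D) / (t_B + t_D)}
#' ranging from -1 (complete avoidance) to 1 (complete preference), and the
#' responsiveness is the total time spent outside the neutral zone,
#' \code{t_B + t_D}.
#'
#' @param session a [PreferenceSession-class].
#' @return List with \code{sop} (NA and \code{defined = FALSE} when the
#'   fish never left the neutral zone), \code{t_B_total}, \code{t_D_total},
#'   \code{responsiveness_s}, \code{defined}.
#' @examples
#' s <- PreferenceSession("f1", "I", data.frame(
#'   interval_index = 1:2, side_of_stimulus1 = c("A", "E"),
#'   t_zoneB_s = c(60, 10), t_zoneC_s = c(30, 80), t_zoneD_s = c(10, 20)))
#' computeSOP(s)$sop
#' @export
computeSOP <- function(session) {
  stopifnot(is(session, "PreferenceSession"))
  df <- session@intervals
  swap <- df$side_of_stimulus1 == "E"
  tB <- ifelse(swap, df$t_zoneD_s, df$t_zoneB_s)
  tD <- ifelse(swap, df$t_zoneB_s, df$t_zoneD_s)
  B <- sum(tB); D <- sum(tD)
  defined <- (B + D) > 0
  list(sop = if (defined) (B - D) / (B + D) else NA_real_,
       t_B_total = B, t_D_total = D,
       responsiveness_s = B + D, defined = defined)
}

#' One-sample preference test against SOP = 0
#'
#' Tests whether a cohort's SOP values differ from the no-preference value
#' of 0 with a one-sample t-test. Undefined SOPs (fish that never entered a
#' preference zone) must be excluded by the caller; NA values are dropped
#' with a warning.
#'
#' @param sops numeric vector of SOP values, at least 3 defined.
#' @return List with \code{statistic}, \code{df}, \code{p_value},
#'   \code{mean_sop}, \code{n}, and \code{degenerate = TRUE} (with NA
#'   statistic) when all values are identical.
#' @export
preferenceTest <- function(sops) {
  if (anyNA(sops)) {
    warning("dropping ", sum(is.na(sops)), " undefined SOP value(s)")
    sops <- sops[!is.na(sops)]
  }
  if (length(sops) < 3L) stop("need at least 3 defined SOP values")
  if (stats::sd(sops) == 0) {
    return(list(statistic = NA_real_, df = length(sops) - 1L,
                p_value = NA_real_, mean_sop = mean(sops),
                n = length(sops), degenerate = TRUE))
  }
  tt <- stats::t.test(sops, mu = 0)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_sop = mean(sops), n = length(sops),
       degenerate = FALSE)
}

.sopTransform <- function(sop, transform) {
  switch(transform,
    arcsine = asin(pmin(pmax(sop, -1), 1)),
    arcsine_sqrt = asin(sqrt((pmin(pmax(sop, -1), 1) + 1) / 2)))
}

.sessionsToTable <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    r <- computeSOP(s)
    data.frame(focal_id = s@focalId, condition = s@condition,
               sop = r$sop, responsiveness_s = r$responsiveness_s,
               defined = r$defined, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-session SOP table
#'
#' One row per session with SOP and responsiveness, the input format of
#' [conditionComparison()] and [responsivenessComparison()].
#'
#' @param sessions list of [PreferenceSession-class] objects.
#' @return data.frame with columns focal_id, condition, sop,
#'   responsiveness_s, defined.
#' @export
sopTable <- function(sessions) .sessionsToTable(sessions)

.rmAnova <- function(df, valueCol) {
  df$condition <- as.factor(df$condition)
  df$focal_id <- as.factor(df$focal_id)
  if (nlevels(df$condition) < 2L) stop("need at least 2 conditions")
  counts <- table(df$focal_id, df$condition)
  if (any(counts == 0)) {
    warning("unbalanced design: some individuals miss conditions; ",
            "fitting with available cases")
  }
  fm <- stats::as.formula(paste(valueCol, "~ condition + (1 | focal_id)"))
  fit <- suppressMessages(lmerTest::lmer(fm, data = df))
  an <- suppressMessages(stats::anova(fit))
  list(fit = fit, f_statistic = an[["F value"]][1],
       p_value = an[["Pr(>F)"]][1])
}

.tukey <- function(fit) {
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Tukey"))
  sm <- summary(gl)
  data.frame(contrast = names(sm$test$coefficients),
             estimate = unname(sm$test$coefficients),
             p_value = unname(sm$test$pvalues),
             stringsAsFactors = FALSE)
}

#' Repeated-measures comparison of SOP across playback conditions
#'
#' Transforms the SOP values (default: \code{asin(SOP)}, defined on the
#' full [-1, 1] range; \code{arcsine_sqrt} of (SOP+1)/2 available as an
#' alternative), fits a repeated-measures ANOVA with individual as a random
#' factor (mixed model), and -- when the omnibus test is significant --
#' performs Tukey HSD pairwise comparisons.
#'
#' @param sessions list of [PreferenceSession-class] objects, or a
#'   data.frame as returned by [sopTable()].
#' @param transform \code{"arcsine"} or \code{"arcsine_sqrt"}.
#' @param tukeyAlpha omnibus significance level gating the post-hoc step.
#' @return List with \code{f_statistic}, \code{p_value}, \code{n_dropped}
#'   (undefined SOPs), and \code{tukey} (data.frame of pairwise contrasts,
#'   or NULL when the omnibus is not significant).
#' @export
conditionComparison <- function(sessions,
                                transform = c("arcsine", "arcsine_sqrt"),
                                tukeyAlpha = 0.05) {
  transform <- match.arg(transform)
  df <- if (is.data.frame(sessions)) sessions else .sessionsToTable(sessions)
  drop <- is.na(df$sop)
  df <- df[!drop, , drop = FALSE]
  df$y <- .sopTransform(df$sop, transform)
  res <- .rmAnova(df, "y")
  tk <- if (!is.na(res$p_value) && res$p_value < tukeyAlpha) {
    .tukey(res$fit)
  } else NULL
  list(f_statistic = res$f_statistic, p_value = res$p_value,
       transform = transform, n_dropped = sum(drop), tukey = tk)
}

#' Repeated-measures comparison of responsiveness across conditions
#'
#' Responsiveness is the total time outside the neutral zone. Times are
#' square-root transformed by default (the conventional
#' variance-stabiliser for durations, defined at 0); literal squaring is
#' available as an alternative reading.
#'
#' @param sessions list of [PreferenceSession-class] objects or a
#'   [sopTable()] data.frame.
#' @param transform \code{"sqrt"} or \code{"square"}.
#' @return List with \code{f_statistic} and \code{p_value}.
#' @export
responsivenessComparison <- function(sessions,
                                     transform = c("sqrt", "square")) {
  transform <- match.arg(transform)
  df <- if (is.data.frame(sessions)) sessions else .sessionsToTable(sessions)
  df$y <- switch(transform, sqrt = sqrt(df$responsiveness_s),
                 square = df$responsiveness_s^2)
  res <- .rmAnova(df, "y")
  list(f_statistic = res$f_statistic, p_value = res$p_value,
       transform = transform)
}

#' Read playback session logs from CSV
#'
#' Expects columns focal_id, condition, interval_index, side_of_stimulus1
#' (A or E), t_zoneB_s, t_zoneC_s, t_zoneD_s; one row per playback
#' interval.
#'
#' @param path CSV file path.
#' @param intervalLengthS playback interval length in seconds.
#' @return List of [PreferenceSession-class] objects, one per focal x
#'   condition.
#' @export
readSessions <- function(path, intervalLengthS = 120) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("focal_id", "condition", "interval_index", "side_of_stimulus1",
            "t_zoneB_s", "t_zoneC_s", "t_zoneD_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("session CSV missing columns: ",
                         paste(miss, collapse = ", "))
  keys <- unique(df[, c("focal_id", "condition")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$focal_id == keys$focal_id[i] &
              df$condition == keys$condition[i], , drop = FALSE]
    sub <- sub[order(sub$interval_index), ]
    PreferenceSession(keys$focal_id[i], keys$condition[i],
                      sub[, need[-(1:2)]], intervalLengthS = intervalLengthS)
  })
}

#' Write a session list to CSV
#'
#' Inverse of [readSessions()]; one row per playback interval.
#'
#' @param sessions list of [PreferenceSession-class] objects.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeSessions <- function(sessions, path) {
  rows <- lapply(sessions, function(s) {
    cbind(data.frame(focal_id = s@focalId, condition = s@condition,
                     stringsAsFactors = FALSE),
          s@intervals)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
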