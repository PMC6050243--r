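# Independent oracles and fixture builders, deliberately naive: each one
# re-derives the quantity from its definition so the fast implementations
# are checked against something that shares no code with them.

# naive double-loop serial correlation: truncated lagged product mean,
# full-sequence mean and population variance
sc_naive <- function(x, max_lag) {
  N <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / N
  sapply(0:max_lag, function(i) {
    acc <- 0
    for (k in 1:(N - i)) acc <- acc + x[k] * x[k + i]
    (acc / (N - i) - m^2) / v
  })
}

# run count straight from the definition: classify pairs, count streaks
runs_naive <- function(x, tol = 0) {
  d <- diff(x)
  cls <- character(length(d))
  for (j in seq_along(d)) {
    cls[j] <- if (abs(d[j]) <= tol) "0" else if (d[j] > 0) "+" else "-"
  }
  runs <- 1
  for (j in seq_along(cls)[-1]) if (cls[j] != cls[j - 1]) runs <- runs + 1
  runs
}

# build a PulseTrain from intervals given in milliseconds
train_from_ipis_ms <- function(ipis_ms, ...) {
  ts <- c(0, cumsum(ipis_ms)) / 1000
  PulseTrain(ts, durationS = max(ts), ...)
}

# a small iid gamma renewal config
renewal_config <- function(mean_ms = 50, sd_ms = 25, duration_s = 120,
                           seed = 1) {
  spiConfig("renewal",
            components = data.frame(weight = 1, location_ms = mean_ms,
                                    scale_ms = sd_ms, family = "gamma"),
            duration_s = duration_s, seed = seed)
}

# two-state sticky config used for memory tests: well-separated state
# means so the between-state variance carries the serial correlation
sticky_config <- function(dwell, duration_s = 120, seed = 1) {
  spiConfig("sticky_state",
            components = data.frame(
              weight = c(0.5, 0.5), location_ms = c(20, 80),
              scale_ms = c(4, 16), family = "lognormal"),
            dwell = dwell, duration_s = duration_s, seed = seed)
}

ar1_config <- function(phi, duration_s = 120, seed = 1) {
  spiConfig("ar1_log",
            components = data.frame(weight = 1, location_ms = 50,
                                    scale_ms = 25, family = "lognormal"),
            phi = phi, duration_s = duration_s, seed = seed)
}
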