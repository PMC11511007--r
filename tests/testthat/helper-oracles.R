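# Independent oracles: deliberately naive recomputations used to check the
# optimized implementation paths.

# Per-grid-step recomputation of the Inactivity Score.  No event-step
# shortcut, no cached activation table: every step rescans the raw event
# vectors.  O(K * E), tolerable only on small fixtures.
oracle_is <- function(stream, config = score_config(), initial = 0) {
  span <- attr(stream, "span")
  step <- config$step
  a <- config$slope
  gamma <- config$gamma
  reg <- attr(stream, "registry")
  t0 <- as.numeric(span[1])
  K <- ceiling((as.numeric(span[2]) - t0) / step)
  ev_t <- as.numeric(stream$timestamp)
  ev_s <- stream$sensor_id
  cert_of <- stats::setNames(reg$certainty, reg$sensor_id)
  vals <- numeric(K + 1)
  vals[1] <- initial
  for (k in 1:K) {
    tk <- t0 + k * step
    in_step <- ev_t > (tk - step) & ev_t <= tk
    rf <- 1
    for (sid in unique(ev_s[in_step])) {
      e_latest <- max(ev_t[in_step & ev_s == sid])
      before <- ev_t[ev_s == sid & ev_t < e_latest]
      l <- if (length(before)) max(before) else NA_real_
      cc <- cert_of[[sid]]
      impact <- if (is.na(l) || (tk - l) >= gamma * (1 - cc)) 1 else (tk - l) / (gamma * (1 - cc))
      rf <- rf * (1 - cc * impact)
    }
    vals[k + 1] <- (vals[k] + a) * rf
  }
  vals
}

# Pointer-walk Duration of Inactivity at grid resolution.
oracle_di <- function(stream, config = score_config()) {
  span <- attr(stream, "span")
  step <- config$step
  t0 <- as.numeric(span[1])
  K <- ceiling((as.numeric(span[2]) - t0) / step)
  ev_k <- sort(unique(ceiling((as.numeric(stream$timestamp) - t0) / step)))
  ev_k <- ev_k[ev_k >= 1]
  vals <- numeric(K + 1)
  last <- 0
  p <- 1
  for (k in 1:K) {
    while (p <= length(ev_k) && ev_k[p] <= k) {
      last <- ev_k[p]
      p <- p + 1
    }
    vals[k + 1] <- config$slope * (k - last)
  }
  vals
}

# Greedy left-to-right per-sensor thinning oracle for the rolling filter.
oracle_rolling_filter_keep <- function(times, sensors, spacing = 3600) {
  keep <- logical(length(times))
  for (sid in unique(sensors)) {
    idx <- which(sensors == sid)
    last <- -Inf
    for (i in idx) {
      if (times[i] - last >= spacing) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
  }
  keep
}

# Nested-loop window maxima oracle.
oracle_window_max <- function(series, refs, beta) {
  t <- as.numeric(series$time)
  vapply(as.numeric(refs), function(r) {
    sel <- t >= r - beta & t <= r + beta
    if (!any(sel)) NA_real_ else max(series$value[sel])
  }, numeric(1))
}

# Two-pass onset oracle: mark every above-threshold point, then keep the
# first point of each run.
oracle_onsets <- function(values, thresholds) {
  above <- !is.na(thresholds) & values > thresholds
  which(above & !c(FALSE, above[-length(above)]))
}

# Truncated-normal mean via the closed form, used against sampled certainties.
truncnorm_mean <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Random small event stream over a handful of sensors.
random_stream <- function(seed, n_events = 50, n_sensors = 3,
                          span_hours = 24, certainty = NULL,
                          start = "2024-03-04 00:00:00") {
  withr::with_seed(seed, {
    if (is.null(certainty)) certainty <- round(runif(n_sensors, 0.2, 1), 2)
    reg <- sensor_registry(paste0("X", seq_len(n_sensors)), certainty)
    t0 <- as.POSIXct(start, tz = "UTC")
    ts <- t0 + sort(floor(runif(n_events, 1, span_hours * 3600)))
    sid <- paste0("X", sample.int(n_sensors, n_events, replace = TRUE))
    event_stream(ts, sid, reg, span = c(t0, t0 + span_hours * 3600))
  })
}
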