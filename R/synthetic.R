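# Synthetic smart-home data: circadian household activity streams, per-sensor
# certainty sampling by noise level, and matched spurious-event noise sets.

noise_level_table <- list(
  N = list(label = "N", mu = 1.00, sigma = 0.00, lower = 1.0, upper = 1.0),
  L = list(label = "L", mu = 0.95, sigma = 0.02, lower = 0.9, upper = 1.0),
  M = list(label = "M", mu = 0.90, sigma = 0.10, lower = 0.8, upper = 1.0),
  H = list(label = "H", mu = 0.85, sigma = 0.20, lower = 0.6, upper = 1.0)
)

#' Noise-level specification
#'
#' Certainty-sampling regimes for simulated unreliable sensors: certainties
#' are drawn from a normal distribution `N(mu, sigma)` and accepted only
#' within `[lower, upper]`.  The four standard levels are
#' `N` (no noise: all certainties 1), `L` (mu 0.95, sigma 0.02, bounds
#' \[0.9, 1\]), `M` (mu 0.90, sigma 0.10, \[0.8, 1\]) and `H` (mu 0.85,
#' sigma 0.20, \[0.6, 1\]).
#'
#' @param label One of `"N"`, `"L"`, `"M"`, `"H"`, or supply the fields
#'   directly for a custom level.
#' @param mu,sigma,lower,upper Custom truncated-normal parameters.
#' @return A list of class `"noise_level"`.
#' @export
#' @examples
#' noise_level("H")
noise_level <- function(label = c("N", "L", "M", "H"),
                        mu = NULL, sigma = NULL, lower = NULL, upper = NULL) {
  if (is.null(mu)) {
    label <- match.arg(label)
    spec <- noise_level_table[[label]]
  } else {
    stopifnot(sigma >= 0, lower <= upper, lower >= 0, upper <= 1)
    spec <- list(label = as.character(label)[1], mu = mu, sigma = sigma,
                 lower = lower, upper = upper)
  }
  structure(spec, class = "noise_level")
}

#' Sample per-sensor certainty values for a noise level
#'
#' Rejection sampling from `N(mu, sigma)` until each value lands within the
#' level's bounds.  The no-noise level is degenerate and returns ones without
#' touching the random-number stream.
#'
#' @param n Number of sensors.
#' @param level A [noise_level()] or its label.
#' @param seed Optional seed; sampling is deterministic given the seed and
#'   does not disturb the caller's RNG state.
#' @return `n` certainties within the level's bounds.
#' @export
#' @examples
#' sample_certainties(5, "H", seed = 1)
sample_certainties <- function(n, level, seed = NULL) {
  stopifnot(n >= 1)
  if (!inherits(level, "noise_level")) level <- noise_level(level)
  if (level$sigma == 0) {
    if (level$mu < level$lower || level$mu > level$upper) {
      stopf("degenerate noise level: mu %.3f outside [%.3f, %.3f]",
            level$mu, level$lower, level$upper)
    }
    return(rep(level$mu, n))
  }
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(max(n, 16L), level$mu, level$sigma)
      out <- c(out, draw[draw >= level$lower & draw <= level$upper])
    }
    out[seq_len(n)]
  })
}

#' Household simulation configuration
#'
#' Describes a synthetic single-occupant household: an inhomogeneous-Poisson
#' activity process with a 24 h periodic (circadian) intensity profile,
#' distributed over sensors by multinomial weights, with an optional
#' weekend activity multiplier.
#'
#' @param n_sensors Number of sensors (default 5).
#' @param days Days to simulate (default 120).
#' @param activity_profile 24 non-negative expected event counts per
#'   hour-of-day at household level.  The default is a two-peak circadian
#'   profile (morning and evening peaks, quiet nights) totalling roughly 37
#'   events/day, comparable to a motion-sensor home after per-sensor hourly
#'   thinning.
#' @param sensor_weights Per-sensor multinomial weights (default uniform);
#'   normalized to sum to 1.
#' @param weekend_scale Multiplier applied to the profile on Saturdays and
#'   Sundays (default 1.2: more time spent at home).
#' @param start Start date (midnight); defaults to `"2024-01-01"` (a Monday).
#' @param seed Integer seed for reproducible streams.
#' @return A list of class `"household_config"`.
#' @export
household_config <- function(n_sensors = 5, days = 120,
                             activity_profile = NULL, sensor_weights = NULL,
                             weekend_scale = 1.2, start = "2024-01-01",
                             seed = 1L) {
  stopifnot(n_sensors >= 1, days >= 1, weekend_scale > 0)
  if (is.null(activity_profile)) {
    activity_profile <- c(rep(0.2, 6),   # 00-05: night
                          rep(3.0, 3),   # 06-08: morning peak
                          rep(1.5, 9),   # 09-17: daytime
                          rep(3.0, 4),   # 18-21: evening peak
                          rep(0.8, 2))   # 22-23: winding down
  }
  stopifnot(length(activity_profile) == 24, all(activity_profile >= 0))
  if (is.null(sensor_weights)) sensor_weights <- rep(1 / n_sensors, n_sensors)
  stopifnot(length(sensor_weights) == n_sensors, all(sensor_weights >= 0),
            sum(sensor_weights) > 0)
  structure(list(n_sensors = as.integer(n_sensors), days = as.integer(days),
                 activity_profile = as.numeric(activity_profile),
                 sensor_weights = as.numeric(sensor_weights) / sum(sensor_weights),
                 weekend_scale = as.numeric(weekend_scale),
                 start = as_time(start), seed = as.integer(seed)),
            class = "household_config")
}

#' Generate a synthetic household activity stream
#'
#' Draws an inhomogeneous Poisson event stream over `days` days with hourly
#' intensity `activity_profile[hour]` (scaled by `weekend_scale` on
#' Saturday/Sunday), assigns each event to a sensor by the multinomial
#' weights, and timestamps events uniformly within their hour (rounded to
#' seconds).  Sensors are named `S1..Sn` with certainty 1 until
#' [assign_certainties()] is applied.
#'
#' @param config A [household_config()].
#' @return An [event_stream()] spanning `[start, start + days]`.
#' @export
#' @examples
#' st <- generate_household_stream(household_config(days = 7, seed = 42))
#' nrow(st)
generate_household_stream <- function(config) {
  stopifnot(inherits(config, "household_config"))
  if (all(config$activity_profile == 0)) {
    warning("all-zero activity profile: generating an empty stream")
  }
  start <- config$start
  hours <- config$days * 24L
  day_idx <- rep(0:(config$days - 1), each = 24L)
  hod <- rep(0:23, config$days)
  wknd <- is_weekend_day((day_of_week(start) + day_idx) %% 7)
  rates <- config$activity_profile[hod + 1] * ifelse(wknd, config$weekend_scale, 1)
  ev <- with_seed(config$seed, {
    counts <- stats::rpois(hours, rates)
    total <- sum(counts)
    hour_start <- secs(start) + (day_idx * 24 + hod) * 3600
    tt <- rep(hour_start, counts) + floor(stats::runif(total, 0, 3600))
    sens <- sample.int(config$n_sensors, total, replace = TRUE,
                       prob = config$sensor_weights)
    list(t = tt, s = sens)
  })
  reg <- sensor_registry(paste0("S", seq_len(config$n_sensors)), certainty = 1)
  sid <- if (length(ev$s)) paste0("S", ev$s) else character(0)
  event_stream(from_secs(ev$t), sid, reg, origin = "real",
               span = c(start, start + config$days * 86400))
}

#' Generate a matched spurious-event noise set
#'
#' For each sensor with certainty `c` and `|s|` genuine events, draws exactly
#' `round((1 - c) * |s|)` spurious events.  A share `1 - global_fraction` of
#' them follows the sensor's empirical hour-of-day activation histogram (noise
#' mimics the times the sensor genuinely fires); the remaining share is
#' uniform over the 24 h clock (time-independent noise).  Calendar days are
#' drawn uniformly over the stream span.
#'
#' @param stream The genuine [event_stream()].
#' @param certainty Per-sensor certainties, named by sensor id or in registry
#'   order; `NULL` (default) uses the certainties already in the stream's
#'   registry.
#' @param global_fraction Share of time-independent noise in `[0, 1]`
#'   (default 0.1).
#' @param seed Optional seed.
#' @return An [event_stream()] of `origin = "noise"` events over the same
#'   registry (updated with `certainty`) and span.
#' @export
generate_noise_events <- function(stream, certainty = NULL,
                                  global_fraction = 0.1, seed = NULL) {
  stopifnot(inherits(stream, "event_stream"),
            global_fraction >= 0, global_fraction <= 1)
  reg <- stream_registry(stream)
  if (!is.null(certainty)) reg <- assign_certainties(reg, certainty)
  span <- stream_span(stream)
  span_sec <- secs(span)
  first_day <- floor(span_sec[1] / 86400)
  last_day <- floor((span_sec[2] - 1e-9) / 86400)
  n_days <- last_day - first_day + 1
  ev_hod <- floor((secs(stream$timestamp) %% 86400) / 3600)
  out_t <- numeric(0)
  out_s <- character(0)
  with_seed(seed, {
    for (i in seq_len(nrow(reg))) {
      sid <- reg$sensor_id[i]
      c_s <- reg$certainty[i]
      idx <- which(stream$sensor_id == sid)
      m <- round((1 - c_s) * length(idx))
      if (m == 0) next
      hist_counts <- tabulate(ev_hod[idx] + 1, nbins = 24)
      tt <- numeric(0)
      while (length(tt) < m) {
        need <- m - length(tt)
        draw_n <- max(need * 2L, 8L)
        uniform <- stats::runif(draw_n) < global_fraction
        hour <- integer(draw_n)
        hour[uniform] <- sample.int(24, sum(uniform), replace = TRUE) - 1L
        if (any(!uniform)) {
          if (sum(hist_counts) == 0) { # sensor never fired: fall back to uniform
            hour[!uniform] <- sample.int(24, sum(!uniform), replace = TRUE) - 1L
          } else {
            hour[!uniform] <- sample.int(24, sum(!uniform), replace = TRUE,
                                         prob = hist_counts) - 1L
          }
        }
        day <- first_day + sample.int(n_days, draw_n, replace = TRUE) - 1L
        cand <- day * 86400 + hour * 3600 + floor(stats::runif(draw_n, 0, 3600))
        cand <- cand[cand >= span_sec[1] & cand <= span_sec[2]]
        tt <- c(tt, cand)
      }
      tt <- tt[seq_len(m)]
      out_t <- c(out_t, tt)
      out_s <- c(out_s, rep(sid, m))
    }
  })
  event_stream(from_secs(out_t), out_s, reg, origin = "noise", span = span)
}
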