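# Inactivity Score: recursive, certainty-weighted inactivity scoring on a
# uniform time grid, plus the classical Duration-of-Inactivity baseline.

#' Scoring configuration
#'
#' The score is computed on a uniform grid of step `step` seconds.  At each
#' step the score gains `slope` (symbolically `a`, in seconds-equivalent;
#' default: the step length, so that an undisturbed score equals elapsed
#' seconds) and is multiplied by a reduction factor derived from the events
#' falling in that step.  `gamma` is the impact-decay horizon: a sensor that
#' re-fires within `gamma * (1 - c)` seconds of its previous activation has
#' proportionally reduced impact.
#'
#' @param step Grid step in seconds (default 60).
#' @param slope Score gained per step (default `step`).
#' @param gamma Impact horizon in seconds (default 4 hours).
#' @return A list of class `"score_config"`.
#' @export
score_config <- function(step = 60, slope = step, gamma = 4 * 3600) {
  stopifnot(step > 0, slope > 0, gamma > 0)
  structure(list(step = as.numeric(step), slope = as.numeric(slope),
                 gamma = as.numeric(gamma)),
            class = "score_config")
}

#' Sensor impact of an activation
#'
#' The impact `I(t, s)` of sensor `s` at grid time `t` down-weights sensors
#' that re-fire shortly after their previous activation: if the previous
#' activation `last` lies within `gamma * (1 - certainty)` seconds of `t`, the
#' impact is the elapsed fraction `(t - last) / (gamma * (1 - certainty))`;
#' otherwise (including a sensor that never fired before, or a fully certain
#' sensor, for which the window has zero length) it is 1.
#'
#' @param t Grid time (`POSIXct` or numeric seconds).
#' @param last Previous activation time of the same sensor, or `NA` if none.
#' @param certainty Sensor certainty in `[0, 1]`.
#' @param gamma Impact horizon in seconds.
#' @return Impact values in `(0, 1]` (vectorized).
#' @export
#' @examples
#' sensor_impact(2880, 0, certainty = 0.6, gamma = 14400) # 2880/5760 = 0.5
sensor_impact <- function(t, last, certainty, gamma) {
  t <- if (inherits(t, "POSIXct")) secs(t) else as.numeric(t)
  last <- if (inherits(last, "POSIXct")) secs(last) else as.numeric(last)
  stopifnot(all(certainty >= 0 & certainty <= 1), gamma > 0)
  n <- max(length(t), length(last), length(certainty))
  t <- rep_len(t, n); last <- rep_len(last, n); certainty <- rep_len(certainty, n)
  if (any(!is.na(last) & last >= t)) stopf("previous activation must precede t")
  window <- gamma * (1 - certainty)
  dt <- t - last
  out <- rep(1, n)
  recent <- !is.na(last) & dt < window # window 0 (certainty 1) is never "recent"
  out[recent] <- dt[recent] / window[recent]
  out
}

#' Reduction factor for one grid step
#'
#' Each sensor that fired during the step contributes a factor
#' `1 - certainty * impact`: a fully certain activation (certainty 1, impact 1)
#' resets the score to zero, an uncertain one only shrinks it, and a rapid
#' re-fire (small impact) leaves it almost untouched.  Factors multiply over
#' the distinct sensors of the step, so simultaneous independent activations
#' reduce the score more than any single one; with no events the factor is 1
#' (empty product) and the score simply grows.
#'
#' @param certainty Certainties of the distinct sensors that fired.
#' @param impact Matching impacts from [sensor_impact()].
#' @param sensor_id Optional ids used to reject duplicate sensors.
#' @return A single reduction factor in `[0, 1]`.
#' @export
#' @examples
#' reduction_factor(numeric(0), numeric(0)) # 1: no events
#' reduction_factor(c(0.8, 0.6), c(1, 1)) # 0.2 * 0.4 = 0.08
reduction_factor <- function(certainty, impact, sensor_id = NULL) {
  stopifnot(length(certainty) == length(impact))
  if (!is.null(sensor_id) && anyDuplicated(sensor_id)) {
    stopf("duplicate sensor in one grid step: impacts must be per distinct sensor")
  }
  stopifnot(all(certainty >= 0 & certainty <= 1), all(impact >= 0 & impact <= 1))
  prod(1 - certainty * impact)
}

# ---- score series container -------------------------------------------------

new_score_series <- function(start, step, values, kind, slope) {
  df <- data.frame(time = from_secs(secs(start) + step * (seq_along(values) - 1)),
                   value = values)
  structure(df, start = as_time(start), step = step, kind = kind, slope = slope,
            class = c("score_series", "data.frame"))
}

#' Build a score series from raw values
#'
#' Mainly useful in tests and when feeding external histories to the threshold
#' machinery.
#'
#' @param start `POSIXct` time of the first grid point.
#' @param step Grid step in seconds.
#' @param values Numeric score values, one per grid point.
#' @param kind `"IS"` or `"DI"`.
#' @param slope Score gained per step (metadata; default `step`).
#' @return A `score_series`.
#' @export
score_series <- function(start, step, values, kind = "IS", slope = step) {
  stopifnot(is.numeric(values), step > 0, kind %in% c("IS", "DI"))
  if (any(values < 0)) stopf("score values must be >= 0")
  new_score_series(as_time(start), step, as.numeric(values), kind, slope)
}

#' @export
print.score_series <- function(x, ...) {
  cat(sprintf("<score_series:%s> %d points, step %gs, %s -- %s\n",
              attr(x, "kind"), nrow(x), attr(x, "step"),
              format(x$time[1], "%Y-%m-%d %H:%M"),
              format(x$time[nrow(x)], "%Y-%m-%d %H:%M")))
  invisible(x)
}

#' Write / read a score series CSV
#'
#' Columns `timestamp,value,kind`; ISO-8601 timestamps.
#'
#' @param series A `score_series`.
#' @param path File path.
#' @export
write_score_csv <- function(series, path) {
  stopifnot(inherits(series, "score_series"))
  df <- data.frame(timestamp = format(series$time, "%Y-%m-%dT%H:%M:%S"),
                   value = series$value, kind = attr(series, "kind"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- core engine ------------------------------------------------------------

# Previous activation time (strictly earlier, same sensor) for each event.
# Events must be in non-decreasing time order.  Ties of one sensor collapse:
# both tied events get the last strictly earlier activation.
prev_activation <- function(ev_t, ev_sensor) {
  prev <- rep(NA_real_, length(ev_t))
  for (idx in split(seq_along(ev_t), ev_sensor)) {
    tt <- ev_t[idx]
    uq <- unique(tt) # sorted, since tt is
    prev_u <- c(NA_real_, uq[-length(uq)])
    prev[idx] <- prev_u[match(tt, uq)]
  }
  prev
}

# Event-step engine: computes score values on grid points t0 + (0:K)*step.
# Events are assigned to steps k = ceiling((t - t0)/step), i.e. step k covers
# (t_{k-1}, t_k]; events exactly at t0 belong to step 0 and only seed the
# activation history.  `ev_prev` carries each event's previous activation time
# (possibly from before t0, for mid-stream restarts).
is_engine <- function(ev_t, ev_cert, ev_sensor, ev_prev,
                      t0, K, step, a, gamma, initial) {
  if (length(ev_t)) {
    k <- ceiling((ev_t - t0) / step)
    if (any(ev_t < t0) || any(k > K)) stopf("event outside the scoring span")
    sel <- k >= 1
    k <- k[sel]
    if (length(k)) {
      # latest firing per (step, sensor): later duplicates supersede earlier
      key <- paste(k, ev_sensor[sel], sep = "\r")
      latest <- !duplicated(key, fromLast = TRUE)
      ks <- k[latest]
      cert <- ev_cert[sel][latest]
      imp <- sensor_impact(t0 + ks * step, ev_prev[sel][latest], cert, gamma)
      fac <- 1 - cert * imp
      spl <- split(fac, ks)
      rf <- vapply(spl, prod, numeric(1))
      ev_steps <- as.numeric(names(spl))
    } else {
      ev_steps <- numeric(0); rf <- numeric(0)
    }
  } else {
    ev_steps <- numeric(0); rf <- numeric(0)
  }
  # recursion visits event steps only; the score is linear in between
  v <- numeric(length(ev_steps))
  v_prev <- initial; k_prev <- 0
  for (j in seq_along(ev_steps)) {
    v[j] <- (v_prev + a * (ev_steps[j] - k_prev)) * rf[j]
    v_prev <- v[j]; k_prev <- ev_steps[j]
  }
  anchors <- c(0, ev_steps)
  anchor_val <- c(initial, v)
  g <- 0:K
  pos <- findInterval(g, anchors)
  anchor_val[pos] + a * (g - anchors[pos])
}

# Shared preparation: event seconds, certainties, previous activations.
prepare_events <- function(stream) {
  reg <- stream_registry(stream)
  ev_t <- secs(stream$timestamp)
  ev_cert <- reg$certainty[match(stream$sensor_id, reg$sensor_id)]
  list(t = ev_t, cert = ev_cert, sensor = stream$sensor_id,
       prev = prev_activation(ev_t, stream$sensor_id))
}

grid_size <- function(span, step) {
  K <- ceiling((secs(span[2]) - secs(span[1])) / step)
  if (K < 1) stopf("stream span must cover at least one grid step")
  K
}

#' Compute the Inactivity Score series
#'
#' Evaluates the recursion `IS(t_k) = (IS(t_{k-1}) + a) * RF(t_k, E_k)` on the
#' uniform grid covering the stream's span, where `E_k` is the set of distinct
#' sensors with at least one event in `(t_{k-1}, t_k]` and `RF` is the product
#' of per-sensor factors `1 - c * I` (see [reduction_factor()],
#' [sensor_impact()]).  All events — genuine and noise-origin alike — update a
#' sensor's activation history, since the detector cannot tell them apart.
#'
#' @param stream An [event_stream()].
#' @param config A [score_config()].
#' @param initial Score at the first grid point (default 0).
#' @return A `score_series` of kind `"IS"`.
#' @export
#' @examples
#' reg <- sensor_registry("A", 0.8)
#' st <- event_stream(as.POSIXct("2024-01-01 00:30:00", tz = "UTC"), "A", reg,
#'                    span = as.POSIXct(c("2024-01-01 00:00:00",
#'                                        "2024-01-01 01:00:00"), tz = "UTC"))
#' inactivity_score(st)
inactivity_score <- function(stream, config = score_config(), initial = 0) {
  stopifnot(inherits(stream, "event_stream"), inherits(config, "score_config"),
            initial >= 0)
  span <- stream_span(stream)
  K <- grid_size(span, config$step)
  ev <- prepare_events(stream)
  vals <- is_engine(ev$t, ev$cert, ev$sensor, ev$prev,
                    secs(span[1]), K, config$step, config$slope, config$gamma,
                    initial)
  new_score_series(span[1], config$step, vals, "IS", config$slope)
}

#' Compute the Duration-of-Inactivity baseline series
#'
#' The classical inactivity measure: elapsed time since the last activity
#' event, at grid resolution.  The score resets to zero at the end of any step
#' containing an event — regardless of the sensor's certainty — and grows by
#' `slope` per step otherwise; before the first event it grows from zero at
#' the span start.  When every sensor has certainty 1 this coincides exactly
#' with [inactivity_score()] on the shared grid.
#'
#' @inheritParams inactivity_score
#' @return A `score_series` of kind `"DI"`.
#' @export
duration_of_inactivity <- function(stream, config = score_config()) {
  stopifnot(inherits(stream, "event_stream"), inherits(config, "score_config"))
  span <- stream_span(stream)
  K <- grid_size(span, config$step)
  t0 <- secs(span[1])
  k <- ceiling((secs(stream$timestamp) - t0) / config$step)
  if (any(k > K) || any(secs(stream$timestamp) < t0)) stopf("event outside the scoring span")
  ev_steps <- sort(unique(k[k >= 1]))
  anchors <- c(0, ev_steps)
  g <- 0:K
  pos <- findInterval(g, anchors)
  vals <- config$slope * (g - anchors[pos])
  new_score_series(span[1], config$step, vals, "DI", config$slope)
}
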