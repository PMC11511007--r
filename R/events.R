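# Domain types and I/O for sensor registries and activity event streams.

#' Sensor registry
#'
#' A registry describes the sensors of one household: an opaque identifier, a
#' certainty `c` in `[0, 1]` (the probability-like weight that an event from
#' that sensor reflects genuine human activity), and an optional room label.
#'
#' @param sensor_id Character vector of unique sensor identifiers.
#' @param certainty Numeric vector in `[0, 1]`, recycled if length 1.
#' @param room Optional character vector of room labels.
#' @return A `data.frame` of class `"sensor_registry"` with columns
#'   `sensor_id`, `certainty`, `room`.
#' @export
#' @examples
#' sensor_registry(c("M007", "M019"), certainty = c(0.9, 0.8))
sensor_registry <- function(sensor_id, certainty = 1, room = NA_character_) {
  sensor_id <- as.character(sensor_id)
  if (anyDuplicated(sensor_id)) {
    stopf("duplicate sensor_id in registry: %s",
          paste(unique(sensor_id[duplicated(sensor_id)]), collapse = ", "))
  }
  certainty <- rep_len(as.numeric(certainty), length(sensor_id))
  if (anyNA(certainty) || any(certainty < 0 | certainty > 1)) {
    stopf("certainty must lie in [0, 1]")
  }
  room <- rep_len(as.character(room), length(sensor_id))
  out <- data.frame(sensor_id = sensor_id, certainty = certainty, room = room,
                    stringsAsFactors = FALSE)
  class(out) <- c("sensor_registry", "data.frame")
  out
}

#' Assign certainty values to a registry or stream
#'
#' @param x A `sensor_registry` or `event_stream`.
#' @param certainty Numeric vector, either named by sensor id or in registry
#'   order.
#' @return `x` with updated certainties.
#' @export
assign_certainties <- function(x, certainty) {
  if (inherits(x, "event_stream")) {
    attr(x, "registry") <- assign_certainties(attr(x, "registry"), certainty)
    return(x)
  }
  stopifnot(inherits(x, "sensor_registry"))
  if (!is.null(names(certainty))) {
    missing <- setdiff(x$sensor_id, names(certainty))
    if (length(missing)) stopf("no certainty supplied for sensor(s): %s", paste(missing, collapse = ", "))
    certainty <- unname(certainty[x$sensor_id])
  }
  sensor_registry(x$sensor_id, certainty, x$room)
}

#' Construct an activity event stream
#'
#' An event stream is a time-ordered sequence of binary activity events over a
#' sensor registry.  Events carry an `origin` flag distinguishing genuine
#' (`"real"`) from spurious (`"noise"`) events; the detector itself never
#' inspects it, but the evaluation protocol does.
#'
#' @param timestamp `POSIXct` (or coercible) event times, second resolution.
#' @param sensor_id Character vector of sensor ids, resolving into `registry`.
#' @param registry A [sensor_registry()].
#' @param origin `"real"` or `"noise"`, recycled.
#' @param span Optional `POSIXct` length-2 start/end; defaults to the event
#'   range.  All events must fall within the span.
#' @return A `data.frame` of class `"event_stream"` with columns `timestamp`,
#'   `sensor_id`, `origin` and attributes `registry` and `span`; rows sorted by
#'   timestamp (stable for ties).
#' @export
#' @examples
#' reg <- sensor_registry("A", 0.8)
#' event_stream(as.POSIXct("2024-01-01 10:00:00", tz = "UTC"), "A", reg)
event_stream <- function(timestamp, sensor_id, registry,
                         origin = "real", span = NULL) {
  stopifnot(inherits(registry, "sensor_registry"))
  timestamp <- as_time(timestamp)
  sensor_id <- as.character(sensor_id)
  n <- length(timestamp)
  if (length(sensor_id) == 1 && n > 1) sensor_id <- rep(sensor_id, n)
  stopifnot(length(sensor_id) == n)
  origin <- rep_len(as.character(origin), n)
  if (!all(origin %in% c("real", "noise"))) stopf("origin must be 'real' or 'noise'")
  unknown <- setdiff(sensor_id, registry$sensor_id)
  if (length(unknown)) stopf("event sensor(s) not in registry: %s", paste(unknown, collapse = ", "))
  ord <- order(timestamp) # stable: ties keep input order
  ev <- data.frame(timestamp = timestamp[ord], sensor_id = sensor_id[ord],
                   origin = origin[ord], stringsAsFactors = FALSE)
  if (is.null(span)) {
    span <- if (n > 0) range(ev$timestamp) else as_time(c("1970-01-01", "1970-01-01"))
  } else {
    span <- as_time(span)
    stopifnot(length(span) == 2, span[1] <= span[2])
    if (n > 0 && (ev$timestamp[1] < span[1] || ev$timestamp[n] > span[2])) {
      stopf("events fall outside the declared span")
    }
  }
  structure(ev, registry = registry, span = span,
            class = c("event_stream", "data.frame"))
}

#' @export
print.event_stream <- function(x, ...) {
  reg <- attr(x, "registry")
  span <- attr(x, "span")
  cat(sprintf("<event_stream> %d events, %d sensors, %s -- %s\n",
              nrow(x), nrow(reg),
              format(span[1], "%Y-%m-%d %H:%M:%S"),
              format(span[2], "%Y-%m-%d %H:%M:%S")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

stream_registry <- function(stream) attr(stream, "registry")
stream_span <- function(stream) attr(stream, "span")

#' Read a CASAS-style whitespace-separated event log
#'
#' Parses lines of the form `"YYYY-MM-DD HH:MM:SS(.ffffff) SENSOR VALUE"`,
#' keeping only events of the requested sensors whose value equals `on_value`
#' (motion-sensor "ON" events, typically).  Lines for other sensors or values
#' are dropped; malformed lines are skipped with a reported count.
#'
#' @param path Path to the log file.
#' @param keep_sensors Character vector of sensor ids to retain.
#' @param on_value Value string an event must match (default `"ON"`).
#' @param certainty Certainties for the kept sensors (default 1), passed to
#'   [sensor_registry()].
#' @return An [event_stream()] sorted by time.
#' @export
read_casas <- function(path, keep_sensors, on_value = "ON", certainty = 1) {
  if (!file.exists(path)) stopf("cannot read event log: %s", path)
  keep_sensors <- as.character(keep_sensors)
  if (!length(keep_sensors)) stopf("no sensors requested: keep_sensors is empty")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  ok <- nf >= 4
  n_malformed <- sum(!ok)
  fields <- fields[ok]
  date <- vapply(fields, `[[`, "", 1L)
  time <- vapply(fields, `[[`, "", 2L)
  sensor <- vapply(fields, `[[`, "", 3L)
  value <- vapply(fields, `[[`, "", 4L)
  # drop fractional seconds: events are kept at second resolution
  time <- sub("\\.[0-9]+$", "", time)
  ts <- as.POSIXct(paste(date, time), tz = iss_tz,
                   tryFormats = c("%Y-%m-%d %H:%M:%S"))
  bad_ts <- is.na(ts)
  n_malformed <- n_malformed + sum(bad_ts)
  if (n_malformed > 0) {
    message(sprintf("read_casas: skipped %d malformed line(s) in %s", n_malformed, path))
  }
  keep <- !bad_ts & sensor %in% keep_sensors & value == on_value
  if (!any(keep)) stopf("no events for the requested sensors/value in %s", path)
  reg <- sensor_registry(keep_sensors, certainty)
  event_stream(ts[keep], sensor[keep], reg, origin = "real")
}

#' One-activation-per-sensor-per-hour rolling filter
#'
#' Thins each sensor's events so that consecutive kept events of the same
#' sensor are at least `spacing` seconds apart (default one hour); the first
#' event of every sensor is always kept.  This suppresses near-continuous
#' motion-sensor triggering while a person merely stays in a room.  The window
#' is half-open: an event exactly `spacing` seconds after the last kept one is
#' kept.
#'
#' @param stream An [event_stream()].
#' @param spacing Minimum spacing in seconds between kept events per sensor.
#' @return A filtered [event_stream()]; idempotent.
#' @export
rolling_hour_filter <- function(stream, spacing = 3600) {
  stopifnot(inherits(stream, "event_stream"), spacing > 0)
  if (nrow(stream) == 0) return(stream)
  t <- secs(stream$timestamp)
  keep <- logical(nrow(stream))
  for (idx in split(seq_len(nrow(stream)), stream$sensor_id)) {
    last <- -Inf
    for (i in idx) { # idx is time-ordered because the stream is sorted
      if (t[i] - last >= spacing) {
        keep[i] <- TRUE
        last <- t[i]
      }
    }
  }
  event_stream(stream$timestamp[keep], stream$sensor_id[keep],
               stream_registry(stream), origin = stream$origin[keep],
               span = stream_span(stream))
}

#' Write / read the canonical event CSV
#'
#' The canonical on-disk form is a CSV with header
#' `timestamp,sensor_id,origin`, ISO-8601 timestamps, one event per row.  A
#' write followed by [read_events_csv()] with the same registry round-trips
#' losslessly.
#'
#' @param stream An [event_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  df <- data.frame(timestamp = format(stream$timestamp, "%Y-%m-%dT%H:%M:%S"),
                   sensor_id = stream$sensor_id, origin = stream$origin,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @param registry A [sensor_registry()] covering the file's sensors.
#' @param span Optional span override (default: event range).
#' @export
read_events_csv <- function(path, registry, span = NULL) {
  if (!file.exists(path)) stopf("cannot read event CSV: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0) {
    return(event_stream(as_time(character(0)), character(0), registry, span = span))
  }
  event_stream(as.POSIXct(df$timestamp, tz = iss_tz, format = "%Y-%m-%dT%H:%M:%S"),
               df$sensor_id, registry, origin = df$origin, span = span)
}

#' Write / read a sensor registry CSV
#'
#' Columns `sensor_id,certainty,room`.
#'
#' @param registry A [sensor_registry()].
#' @param path File path.
#' @return `path` (write) or a `sensor_registry` (read).
#' @export
write_registry_csv <- function(registry, path) {
  stopifnot(inherits(registry, "sensor_registry"))
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_registry_csv
#' @export
read_registry_csv <- function(path) {
  if (!file.exists(path)) stopf("cannot read registry CSV: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sensor_registry(df$sensor_id, df$certainty, df$room %||% NA_character_)
}

#' Merge a real stream with a noise stream
#'
#' Events are pooled and re-sorted; the span is the union.  Both streams must
#' share one registry (same sensor ids and certainties).
#'
#' @param real,noise [event_stream()] objects.
#' @return A merged [event_stream()].
#' @export
merge_streams <- function(real, noise) {
  stopifnot(inherits(real, "event_stream"), inherits(noise, "event_stream"))
  reg_a <- stream_registry(real)
  reg_b <- stream_registry(noise)
  if (!identical(reg_a$sensor_id, reg_b$sensor_id) ||
      !isTRUE(all.equal(reg_a$certainty, reg_b$certainty))) {
    stopf("streams have different registries")
  }
  span <- c(min(stream_span(real)[1], stream_span(noise)[1]),
            max(stream_span(real)[2], stream_span(noise)[2]))
  event_stream(c(real$timestamp, noise$timestamp),
               c(real$sensor_id, noise$sensor_id), reg_a,
               origin = c(real$origin, noise$origin), span = span)
}

#' Split a stream at large data gaps
#'
#' Recording outages masquerade as inactivity; this utility splits a stream
#' into contiguous segments wherever consecutive events (any sensor) are more
#' than `max_gap` seconds apart, so each segment can be scored on its own.
#'
#' @param stream An [event_stream()].
#' @param max_gap Gap limit in seconds (default one hour).
#' @return A list of [event_stream()] segments, each spanning its own events.
#' @export
split_at_gaps <- function(stream, max_gap = 3600) {
  stopifnot(inherits(stream, "event_stream"), max_gap > 0)
  n <- nrow(stream)
  if (n <= 1) return(list(stream))
  t <- secs(stream$timestamp)
  seg <- cumsum(c(0, diff(t) > max_gap))
  lapply(split(seq_len(n), seg), function(idx) {
    event_stream(stream$timestamp[idx], stream$sensor_id[idx],
                 stream_registry(stream), origin = stream$origin[idx])
  })
}
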