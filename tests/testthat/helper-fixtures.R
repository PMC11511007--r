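# Shared fixtures built in code.

# The four-sensor worked example: certainties 0.8 / 0.6 / 0.9 / 0.3, seven
# events between 06:32 and 09:56, scored on a 06:00-10:00 grid.
worked_example_stream <- function() {
  reg <- sensor_registry(paste0("Sensor-", 1:4), c(0.6, 0.9, 0.3, 0.8))
  ts <- as.POSIXct(paste("2024-01-01",
                         c("06:32:00", "06:48:00", "06:53:00", "07:13:00",
                           "07:20:00", "08:13:00", "09:56:00")), tz = "UTC")
  sid <- c("Sensor-4", "Sensor-1", "Sensor-1", "Sensor-1",
           "Sensor-2", "Sensor-3", "Sensor-1")
  event_stream(ts, sid, reg,
               span = as.POSIXct(c("2024-01-01 06:00:00",
                                   "2024-01-01 10:00:00"), tz = "UTC"))
}

# A small, fast detector configuration for tests that need thresholds but not
# the full 10-week initialization: 2-week init, 14-day look-back.
fast_detector <- function(...) {
  detector_config(psi_days = 14, init_period = 14 * 86400, ...)
}

# A plausible filtered household stream for evaluation tests; 100 days
# leaves 30 evaluated days after the default 10-week initialization.
eval_household <- function(seed = 101, days = 100) {
  rolling_hour_filter(generate_household_stream(
    household_config(days = days, seed = seed)))
}

# An event-free noise stream over the same registry and span.
empty_noise <- function(stream) {
  event_stream(as.POSIXct(character(0), tz = "UTC"), character(0),
               attr(stream, "registry"), span = attr(stream, "span"))
}

# A constant-valued score history over whole days, step 1 h (fast).
constant_history <- function(days = 30, value = 100, step = 3600,
                             start = "2024-01-01") {
  score_series(as.POSIXct(start, tz = "UTC"), step,
               rep(value, days * 86400 / step + 1))
}
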