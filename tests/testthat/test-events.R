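test_that("registry validation rejects bad certainties and duplicate ids", {
  expect_error(sensor_registry(c("A", "A"), 0.5), "duplicate")
  expect_error(sensor_registry("A", 1.2), "certainty")
  expect_error(sensor_registry("A", -0.1), "certainty")
  reg <- sensor_registry(c("A", "B"), c(0, 1), room = c("hall", NA))
  expect_s3_class(reg, "sensor_registry")
  expect_error(event_stream(Sys.time(), "C", reg), "not in registry")
})

test_that("CASAS reader keeps only requested sensors' ON events", {
  demo <- system.file("extdata", "demo_casas.txt", package = "inactivityscore")
  st <- suppressMessages(read_casas(demo, keep_sensors = "M004"))
  expect_equal(nrow(st), 1L)
  expect_equal(st$sensor_id, "M004")
  st4 <- suppressMessages(read_casas(demo, keep_sensors = c("M001", "M002", "M003", "M004")))
  expect_equal(nrow(st4), 7L) # OFF events and the temperature line dropped
  expect_error(read_casas(demo, keep_sensors = character(0)), "empty")
  expect_error(read_casas(demo, keep_sensors = "M099"), "no events")
  expect_error(read_casas("/nonexistent/file", "M001"), "cannot read")
})

test_that("CASAS reader re-sorts disordered lines and reports malformed ones", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2024-01-01 10:30:00 A ON",
               "2024-01-01 10:00:00 A ON", # out of order
               "garbage line",
               "2024-01-01 11:00:00 A ON"), f)
  expect_message(st <- read_casas(f, "A"), "skipped 1 malformed")
  expect_equal(nrow(st), 3L)
  expect_false(is.unsorted(st$timestamp))
  expect_equal(format(st$timestamp[1], "%H:%M"), "10:00")
})

test_that("rolling filter keeps one activation per sensor per hour", {
  reg <- sensor_registry(c("A", "B"))
  t0 <- as.POSIXct("2024-01-01 10:00:00", tz = "UTC")
  # exactly 1 h later is kept (half-open window), 30 min later is not
  st <- event_stream(t0 + c(0, 1800, 3601), "A", reg)
  kept <- rolling_hour_filter(st)
  expect_equal(as.numeric(kept$timestamp) - as.numeric(t0), c(0, 3601))
  st2 <- event_stream(t0 + c(0, 3600), "A", reg)
  expect_equal(nrow(rolling_hour_filter(st2)), 2L)
  # sensors are filtered independently
  st3 <- event_stream(t0 + c(0, 1800, 2700), c("A", "B", "A"), reg)
  kept3 <- rolling_hour_filter(st3)
  expect_equal(kept3$sensor_id, c("A", "B"))
})

test_that("rolling filter matches the greedy oracle and is idempotent", {
  withr::with_seed(42, {
    reg <- sensor_registry("A")
    t0 <- as.POSIXct("2024-01-01", tz = "UTC")
    ts <- t0 + sort(floor(runif(1000, 0, 86400)))
    st <- event_stream(ts, rep("A", 1000), reg)
    kept <- rolling_hour_filter(st)
    oracle_keep <- oracle_rolling_filter_keep(as.numeric(st$timestamp), st$sensor_id)
    expect_equal(nrow(kept), sum(oracle_keep))
    expect_equal(as.numeric(kept$timestamp), as.numeric(st$timestamp)[oracle_keep])
    # never increases counts; all inter-event gaps >= 1 h per sensor
    expect_lte(nrow(kept), nrow(st))
    expect_true(all(diff(as.numeric(kept$timestamp)) >= 3600))
    # idempotent
    expect_identical(rolling_hour_filter(kept)$timestamp, kept$timestamp)
  })
})

test_that("canonical CSV round-trips streams, including empty and noise", {
  st <- worked_example_stream()
  f <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(st, f)
  back <- read_events_csv(f, attr(st, "registry"), span = attr(st, "span"))
  expect_equal(back$timestamp, st$timestamp)
  expect_equal(back$sensor_id, st$sensor_id)
  expect_equal(back$origin, st$origin)
  # empty stream -> header-only file
  reg <- sensor_registry("A")
  empty <- event_stream(as.POSIXct(character(0), tz = "UTC"), character(0), reg)
  write_events_csv(empty, f)
  expect_equal(readLines(f), "timestamp,sensor_id,origin")
  expect_equal(nrow(read_events_csv(f, reg)), 0L)
  # noise origin preserved
  noisy <- event_stream(st$timestamp, st$sensor_id, attr(st, "registry"),
                        origin = rep(c("real", "noise"), length.out = nrow(st)))
  write_events_csv(noisy, f)
  expect_equal(read_events_csv(f, attr(st, "registry"))$origin, noisy$origin)
})

test_that("registry CSV round-trips", {
  reg <- sensor_registry(c("A", "B"), c(0.25, 1), room = c("hall", NA))
  f <- withr::local_tempfile(fileext = ".csv")
  write_registry_csv(reg, f)
  back <- read_registry_csv(f)
  expect_equal(back$sensor_id, reg$sensor_id)
  expect_equal(back$certainty, reg$certainty)
})

test_that("merging preserves order and split_at_gaps cuts at outages", {
  reg <- sensor_registry("A", 0.9)
  t0 <- as.POSIXct("2024-01-01", tz = "UTC")
  real <- event_stream(t0 + c(100, 5000), c("A", "A"), reg)
  noise <- event_stream(t0 + c(50, 200), c("A", "A"), reg, origin = "noise")
  m <- merge_streams(real, noise)
  expect_false(is.unsorted(m$timestamp))
  expect_equal(m$origin, c("noise", "real", "noise", "real"))
  segs <- split_at_gaps(m, max_gap = 3600)
  expect_length(segs, 2L)
  expect_equal(nrow(segs[[1]]), 3L)
})
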