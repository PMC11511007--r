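test_that("reference times enumerate weekend-matched days at the same clock time", {
  # Wednesday query, one-week horizon: the five preceding weekdays
  wed <- as.POSIXct("2024-01-10 14:00:00", tz = "UTC")
  refs <- reference_times(wed, psi_days = 7)
  expect_length(refs, 5L)
  expect_true(all(format(refs, "%H:%M") == "14:00"))
  expect_true(all(!is_weekend(refs)))
  expect_equal(min(refs), wed - 7 * 86400) # previous Wednesday included
  # Saturday query: previous Sunday and Saturday only
  sat <- as.POSIXct("2024-01-13 09:00:00", tz = "UTC")
  refs_w <- reference_times(sat, psi_days = 7)
  expect_length(refs_w, 2L)
  expect_true(all(is_weekend(refs_w)))
  # 70-day horizon: 50 weekday / 20 weekend references
  expect_length(reference_times(wed, 70), 50L)
  expect_length(reference_times(sat, 70), 20L)
})

test_that("window maxima agree with the nested-loop oracle", {
  h <- constant_history(days = 10, value = 5)
  refs <- attr(h, "start") + c(2, 4, 6) * 86400
  expect_equal(window_maxima(h, refs, beta = 3600), rep(5, 3))
  # a single one-step spike inside +/- beta is picked up
  v <- h$value
  v[49] <- 50 # 2024-01-03 00:00 + 48 steps of 1 h
  h2 <- score_series(attr(h, "start"), 3600, v)
  spike_t <- h2$time[49]
  expect_equal(window_maxima(h2, spike_t + 1800, beta = 3600), 50)
  # random history, many refs
  withr::with_seed(5, {
    vr <- runif(24 * 20, 0, 100)
    hr <- score_series(as.POSIXct("2024-02-01", tz = "UTC"), 3600, vr)
    refs_r <- as.POSIXct("2024-02-03", tz = "UTC") + runif(10, 0, 15 * 86400)
    expect_equal(window_maxima(hr, refs_r, beta = 7200),
                 oracle_window_max(hr, refs_r, 7200))
  })
  expect_error(window_maxima(h, as.POSIXct(character(0)), 3600), "no reference")
})

test_that("IQR upper bound uses interpolated quartiles and clips outliers", {
  expect_equal(iqr_upper_bound(c(1, 2, 3, 4)), 3.25 + 1.5 * 1.5)
  expect_equal(iqr_upper_bound(rep(7, 12)), 7)
  expect_equal(iqr_upper_bound(c(0, 0, 0, 0, 100)), 0) # Q1 = Q3 = 0
  expect_error(iqr_upper_bound(numeric(0)), "no values")
})

test_that("threshold reduces to alpha times the constant history level", {
  h <- constant_history(days = 30, value = 80)
  cfg <- fast_detector(alpha = 2)
  t <- attr(h, "start") + 17 * 86400 + 5 * 3600 # a Thursday, past init
  expect_equal(compute_threshold(h, t, cfg), 160)
  # inside the initialization period: undefined
  expect_true(is.na(compute_threshold(h, attr(h, "start") + 86400, cfg)))
})

test_that("a single outlier maximum is clipped to the IQR bound", {
  # history constant at m except one reference day carrying a huge spike
  start <- as.POSIXct("2024-01-01", tz = "UTC") # Monday
  v <- rep(10, 40 * 24 + 1)
  h <- score_series(start, 3600, v)
  t <- start + 37 * 86400 + 11 * 3600 # a Wednesday 11:00
  cfg <- detector_config(psi_days = 14, init_period = 21 * 86400, alpha = 2)
  refs <- reference_times(t, 14)
  v2 <- v
  spike_idx <- round((as.numeric(refs[1]) - as.numeric(start)) / 3600) + 1
  v2[spike_idx] <- 1e6
  h2 <- score_series(start, 3600, v2)
  vals <- window_maxima(h2, refs, cfg$beta, query_time = t)
  theta <- iqr_upper_bound(vals)
  expect_lt(theta, 1e6)
  expect_equal(compute_threshold(h2, t, cfg), theta * 2)
  # without the spike: plain m * alpha
  expect_equal(compute_threshold(h, t, cfg), 20)
})

test_that("vectorized threshold series equals the per-query computation", {
  withr::with_seed(31, {
    start <- as.POSIXct("2024-01-01", tz = "UTC")
    v <- 1000 + 500 * sin(2 * pi * (0:(35 * 24)) / 24) + runif(35 * 24 + 1, 0, 300)
    h <- score_series(start, 3600, v)
    cfg <- fast_detector()
    ths <- threshold_series(h, cfg)
    probe <- seq(1, nrow(h), by = 37)
    slow <- vapply(h$time[probe], function(tt) compute_threshold(h, tt, cfg),
                   numeric(1))
    expect_equal(ths$threshold[probe], slow)
  })
})

test_that("thresholds are causal, alpha-monotone, clipped, weekend-separated", {
  withr::with_seed(8, {
    start <- as.POSIXct("2024-01-01", tz = "UTC")
    v <- runif(30 * 24 + 1, 0, 1000)
    h <- score_series(start, 3600, v)
    t <- start + 25 * 86400 + 13 * 3600
    cfg <- fast_detector()
    base <- compute_threshold(h, t, cfg)
    # causality: wiping all scores at/after t changes nothing
    k <- round((as.numeric(t) - as.numeric(start)) / 3600)
    v_trunc <- v
    v_trunc[(k + 1):length(v)] <- 0
    expect_equal(compute_threshold(score_series(start, 3600, v_trunc), t, cfg), base)
    # alpha monotonicity
    expect_gte(compute_threshold(h, t, fast_detector(alpha = 4)), base)
    # clipping: threshold never exceeds Theta * alpha
    refs <- reference_times(t, cfg$psi_days)
    vals <- window_maxima(h, refs[refs >= start], cfg$beta, query_time = t)
    expect_lte(base, iqr_upper_bound(vals) * cfg$alpha + 1e-9)
    # weekend separation: perturbing weekend scores leaves weekday thresholds
    wknd <- is_weekend(h$time)
    v_pert <- ifelse(wknd, v * 10, v)
    expect_equal(compute_threshold(score_series(start, 3600, v_pert), t, cfg), base)
  })
})

test_that("alarm onsets fire once per excursion at oracle-identified points", {
  # constant history at 100 with three engineered one-hour excursions
  start <- as.POSIXct("2024-01-01", tz = "UTC")
  n <- 40 * 24 + 1
  v <- rep(100, n)
  cfg <- fast_detector(alpha = 2)
  exc <- c(21 * 24 + 12, 25 * 24 + 4, 30 * 24 + 16) # weekday excursions
  for (e in exc) v[e:(e + 2)] <- 500 # 3 h above any threshold
  h <- score_series(start, 3600, v)
  on <- detect_alarm_onsets(h, cfg)
  ths <- threshold_series(h, cfg)
  expect_equal(match(on$timestamp, h$time), oracle_onsets(v, ths$threshold))
  expect_equal(nrow(on), 3L) # one onset per excursion despite 3 h above
  expect_true(all(on$score > on$threshold))
  # scores never above thresholds: no onsets
  low <- score_series(start, 3600, rep(10, n))
  # thresholds of `low` are 20 everywhere post-init; keep scores at 10
  expect_equal(nrow(detect_alarm_onsets(low, cfg)), 0L)
})

test_that("undefined thresholds never alarm during the initialization period", {
  start <- as.POSIXct("2024-01-01", tz = "UTC")
  v <- c(rep(1e6, 10 * 24), rep(1, 20 * 24 + 1)) # wild scores, but pre-init
  h <- score_series(start, 3600, v)
  cfg <- fast_detector()
  ths <- threshold_series(h, cfg)
  pre <- as.numeric(h$time - start, units = "secs") < cfg$init_period
  expect_true(all(is.na(ths$threshold[pre])))
  on <- detect_alarm_onsets(h, cfg)
  expect_true(all(on$timestamp >= start + cfg$init_period))
})
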