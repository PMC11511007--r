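# Evaluation protocols: false-positive counting on emergency-free streams and
# detection latency for simulated emergencies (activity stops at te, noise
# keeps flowing), with multi-noise-level studies.

#' Count false positives on an emergency-free stream
#'
#' Scores the stream, derives thresholds, and counts alarm onsets after the
#' initialization period.  Since the input contains no genuine emergencies,
#' every onset is a false positive.
#'
#' @param stream An [event_stream()] (real events, or real merged with noise)
#'   whose span exceeds the detector's initialization period.
#' @param score A [score_config()].
#' @param detector A [detector_config()].
#' @return A list of class `"fp_report"`: `onsets` (data frame), `n_fp`,
#'   `fp_per_day` (onsets per post-initialization day), `evaluated_days`.
#' @export
count_false_positives <- function(stream, score = score_config(),
                                  detector = detector_config()) {
  span <- stream_span(stream)
  post_sec <- secs(span[2]) - secs(span[1]) - detector$init_period
  if (post_sec <= 0) {
    stopf("stream span (%.1f days) does not exceed the initialization period (%.1f days)",
          (secs(span[2]) - secs(span[1])) / 86400,
          detector$init_period / 86400)
  }
  is_series <- inactivity_score(stream, score)
  onsets <- detect_alarm_onsets(is_series, detector)
  structure(list(onsets = onsets, n_fp = nrow(onsets),
                 fp_per_day = nrow(onsets) / (post_sec / 86400),
                 evaluated_days = post_sec / 86400),
            class = "fp_report")
}

#' @export
print.fp_report <- function(x, ...) {
  cat(sprintf("<fp_report> %d false-positive onset(s) over %.1f evaluated days (%.3f/day)\n",
              x$n_fp, x$evaluated_days, x$fp_per_day))
  invisible(x)
}

# ---- detection-time machinery ----------------------------------------------

# Precomputations shared by all simulated emergencies on one dataset: the
# merged-stream score, its windowed maxima, and per-sensor event time lists.
detection_context <- function(real, noise, score, detector) {
  merged <- merge_streams(real, noise)
  span <- stream_span(merged)
  step <- score$step
  if (abs(86400 / step - round(86400 / step)) > 1e-9) {
    stopf("the evaluation requires a grid step dividing one day")
  }
  if (detector$beta + step > 86400) {
    stopf("the evaluation requires beta below one day")
  }
  t0 <- secs(span[1])
  K <- grid_size(span, step)
  ev <- prepare_events(merged)
  base_vals <- is_engine(ev$t, ev$cert, ev$sensor, ev$prev, t0, K,
                         step, score$slope, score$gamma, 0)
  w <- round(detector$beta / step)
  list(span = span, t0 = t0, K = K, step = step, w = w,
       spd = round(86400 / step),
       sc = score, dc = detector,
       ev = ev, noise_flag = merged$origin == "noise",
       base_vals = base_vals,
       W_full = slide_max(base_vals, w),
       sensor_times = split(ev$t, ev$sensor))
}

# One simulated emergency at te (POSIXct or seconds) against a context.
run_trial <- function(ctx, te) {
  te_s <- secs(as_time(te))
  dc <- ctx$dc; sc <- ctx$sc
  if (te_s < ctx$t0 + dc$init_period || te_s > secs(ctx$span[2])) {
    stopf("emergency time must fall after the initialization period and within the span")
  }
  step <- ctx$step
  i_e <- floor((te_s - ctx$t0) / step)
  get_W_full <- function(js) ctx$W_full[js + 1]
  thr_e <- threshold_engine(get_W_full, ctx$K + 1, ctx$t0, step, dc, i_e)
  if (!is.na(thr_e) && ctx$base_vals[i_e + 1] > thr_e) {
    return(list(te = from_secs(te_s), tdetect = from_secs(NA_real_),
                delta = NA_real_, status = "excluded_in_alarm"))
  }
  cap_steps <- round(7 * 86400 / step)
  k_max <- i_e + cap_steps
  t_seg0 <- ctx$t0 + i_e * step
  # post-te inputs: noise keeps flowing, genuine activity stops at te
  sel <- ctx$ev$t > t_seg0 & ctx$ev$t <= ctx$t0 + k_max * step &
    (ctx$noise_flag | ctx$ev$t < te_s)
  sub_t <- ctx$ev$t[sel]
  sub_sensor <- ctx$ev$sensor[sel]
  sub_cert <- ctx$ev$cert[sel]
  # previous activations: carry in each sensor's last firing at or before the
  # segment start, then chain within the segment
  sub_prev <- rep(NA_real_, length(sub_t))
  for (sid in unique(sub_sensor)) {
    idx <- which(sub_sensor == sid)
    st <- ctx$sensor_times[[sid]]
    pos <- findInterval(t_seg0, st)
    carry <- if (pos >= 1) st[pos] else NA_real_
    tt <- sub_t[idx]
    uq <- unique(tt)
    prev_u <- c(carry, uq[-length(uq)])
    sub_prev[idx] <- prev_u[match(tt, uq)]
  }
  seg_vals <- is_engine(sub_t, sub_cert, sub_sensor, sub_prev,
                        t_seg0, cap_steps, step, sc$slope, sc$gamma,
                        initial = ctx$base_vals[i_e + 1])
  # windowed maxima: identical to the full stream up to i_e - w, recomputed on
  # the emergency segment afterwards
  w <- ctx$w
  c_lo <- max(i_e - 2 * w, 0)
  vals_comb <- c(ctx$base_vals[(c_lo + 1):(i_e + 1)], seg_vals[-1])
  W_seg <- slide_max(vals_comb, w)
  get_W <- function(js) {
    out <- numeric(length(js))
    left <- js < (i_e - w)
    out[left] <- ctx$W_full[js[left] + 1]
    out[!left] <- W_seg[js[!left] - c_lo + 1]
    out
  }
  k_start <- ceiling((te_s - ctx$t0) / step)
  k_detect <- NA_real_
  chunk <- ctx$spd %/% 2
  k <- k_start
  while (k <= k_max) {
    kk <- k:min(k + chunk - 1, k_max)
    thr <- threshold_engine(get_W, k_max + 1, ctx$t0, step, dc, kk)
    hit <- which(!is.na(thr) & seg_vals[kk - i_e + 1] > thr)
    if (length(hit)) {
      k_detect <- kk[hit[1]]
      break
    }
    k <- k + chunk
  }
  if (is.na(k_detect) || (k_detect * step + ctx$t0 - te_s) > 7 * 86400) {
    return(list(te = from_secs(te_s), tdetect = from_secs(NA_real_),
                delta = NA_real_, status = "censored_7d"))
  }
  list(te = from_secs(te_s), tdetect = from_secs(ctx$t0 + k_detect * step),
       delta = ctx$t0 + k_detect * step - te_s, status = "detected")
}

#' Simulate a single emergency and measure its detection
#'
#' Emulates an emergency at time `te` by truncating genuine activity there
#' while spurious (noise-origin) events keep flowing, then reports the first
#' grid time at or after `te` whose Inactivity Score exceeds its threshold.
#' A trial already above threshold at `te` is excluded; detection more than
#' 7 days after `te` counts as censored.
#'
#' @param real Genuine-activity [event_stream()] (certainties assigned).
#' @param noise Matching noise [event_stream()] (may be empty).
#' @param te Emergency onset time, after the initialization period.
#' @param score,detector A [score_config()] and a [detector_config()].
#' @return A list: `te`, `tdetect` (`NA` if not detected), `delta` seconds,
#'   `status` in `detected` / `censored_7d` / `excluded_in_alarm`.
#' @export
simulate_emergency <- function(real, noise, te,
                               score = score_config(),
                               detector = detector_config()) {
  ctx <- detection_context(real, noise, score, detector)
  run_trial(ctx, te)
}

trials_to_frame <- function(trials) {
  data.frame(te = from_secs(vapply(trials, function(x) secs(x$te), 0)),
             tdetect = from_secs(vapply(trials, function(x) secs(x$tdetect), 0)),
             delta = vapply(trials, function(x) x$delta, 0),
             status = vapply(trials, function(x) x$status, ""),
             stringsAsFactors = FALSE)
}

make_eval_report <- function(trials_df) {
  det <- trials_df$delta[trials_df$status == "detected"]
  structure(list(trials = trials_df,
                 n_trials = nrow(trials_df),
                 n_detected = sum(trials_df$status == "detected"),
                 n_censored = sum(trials_df$status == "censored_7d"),
                 n_excluded = sum(trials_df$status == "excluded_in_alarm"),
                 mean_delta = if (length(det)) mean(det) else NA_real_,
                 median_delta = if (length(det)) stats::median(det) else NA_real_),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt_h <- function(s) if (is.na(s)) "NA" else sprintf("%02d:%02d:%02d h", s %/% 3600, (s %% 3600) %/% 60, round(s %% 60))
  cat(sprintf("<eval_report> %d trials: %d detected, %d censored (7d), %d excluded\n",
              x$n_trials, x$n_detected, x$n_censored, x$n_excluded))
  cat(sprintf("  mean detection time   %s\n  median detection time %s\n",
              fmt_h(x$mean_delta), fmt_h(x$median_delta)))
  invisible(x)
}

#' Run a detection-time study over many simulated emergencies
#'
#' Draws `n_trials` emergency onset times uniformly over the post-
#' initialization span (seeded), simulates each one independently
#' ([simulate_emergency()] semantics, with shared precomputation), and
#' aggregates detection times and statuses.
#'
#' @inheritParams simulate_emergency
#' @param n_trials Number of simulated emergencies (>= 1).
#' @param seed Seed for the onset-time draw.
#' @param te Optional explicit onset times overriding the uniform draw.
#' @return An `"eval_report"`: per-trial table plus mean/median detection
#'   time over detected trials and censoring/exclusion counts.
#' @export
run_detection_time_study <- function(real, noise, n_trials = 100, seed = 1,
                                     score = score_config(),
                                     detector = detector_config(),
                                     te = NULL) {
  ctx <- detection_context(real, noise, score, detector)
  if (is.null(te)) {
    stopifnot(n_trials >= 1)
    lo <- ctx$t0 + detector$init_period
    hi <- secs(ctx$span[2])
    if (hi <= lo) stopf("no post-initialization span to place emergencies in")
    te <- with_seed(seed, from_secs(floor(stats::runif(n_trials, lo, hi))))
  }
  trials <- lapply(te, function(x) run_trial(ctx, x))
  make_eval_report(trials_to_frame(trials))
}

#' Re-verify a detected trial by full recomputation
#'
#' Independently rebuilds the emergency's input (genuine events before `te`
#' plus the complete noise stream), recomputes the score and threshold series
#' from scratch, and checks the detection definition post hoc: the score
#' exceeds the threshold at `tdetect` and at no earlier grid point in
#' `[te, tdetect)`.
#'
#' @param trial A trial from [simulate_emergency()] /
#'   [run_detection_time_study()] (status `"detected"`).
#' @param real,noise The streams the trial was run on.
#' @param score,detector A [score_config()] and a [detector_config()].
#' @return `TRUE` if the trial verifies, otherwise `FALSE` with attribute
#'   `"reason"`.
#' @export
verify_detection <- function(trial, real, noise,
                             score = score_config(),
                             detector = detector_config()) {
  if (trial$status != "detected") stopf("only detected trials can be verified")
  te_s <- secs(trial$te)
  td_s <- secs(trial$tdetect)
  merged <- merge_streams(real, noise)
  keep <- merged$origin == "noise" | secs(merged$timestamp) < te_s
  span <- c(stream_span(merged)[1],
            from_secs(max(secs(stream_span(merged)[2]), td_s + score$step)))
  truncated <- event_stream(merged$timestamp[keep], merged$sensor_id[keep],
                            stream_registry(merged), origin = merged$origin[keep],
                            span = span)
  is_series <- inactivity_score(truncated, score)
  t0 <- secs(attr(is_series, "start"))
  step <- attr(is_series, "step")
  k_first <- ceiling((te_s - t0) / step)
  k_det <- round((td_s - t0) / step)
  at <- from_secs(t0 + (k_first:k_det) * step)
  ths <- threshold_series(is_series, detector, at = at)
  v <- is_series$value[(k_first:k_det) + 1]
  above <- !is.na(ths$threshold) & v > ths$threshold
  if (!above[length(above)]) {
    return(structure(FALSE, reason = "score does not exceed threshold at tdetect"))
  }
  if (any(above[-length(above)])) {
    return(structure(FALSE, reason = "score already exceeded threshold before tdetect"))
  }
  TRUE
}

#' Run the full study across noise levels
#'
#' Generates one synthetic household, then for each noise level samples
#' per-sensor certainties, builds the matched noise set, and runs both
#' evaluation protocols: false-positive counting on the merged stream and a
#' detection-time study with a shared set of emergency onset times (shared
#' across levels for variance reduction).
#'
#' @param config A [household_config()]; its seed fixes the household.
#' @param levels Noise-level labels to run (default all four).
#' @param n_trials Simulated emergencies per level.
#' @param seed Base seed for onset times, certainties and noise sets.
#' @param score,detector A [score_config()] and a [detector_config()].
#' @param global_fraction Time-independent share of the noise sets.
#' @return A list of class `"noise_level_study"`: per-level results
#'   (`certainties`, `fp`, `detection`) and a `summary` data frame with one
#'   row per level.
#' @export
run_noise_level_study <- function(config = household_config(),
                                  levels = c("N", "L", "M", "H"),
                                  n_trials = 100, seed = 1,
                                  score = score_config(),
                                  detector = detector_config(),
                                  global_fraction = 0.1) {
  base <- rolling_hour_filter(generate_household_stream(config))
  t0 <- secs(stream_span(base)[1])
  hi <- secs(stream_span(base)[2])
  lo <- t0 + detector$init_period
  if (hi <= lo) stopf("household span does not exceed the initialization period")
  te <- with_seed(derive_seed(seed, 1), from_secs(floor(stats::runif(n_trials, lo, hi))))
  results <- list()
  for (i in seq_along(levels)) {
    lev <- levels[i]
    certs <- sample_certainties(config$n_sensors, lev, seed = derive_seed(seed, 10 + i))
    real <- assign_certainties(base, stats::setNames(certs, stream_registry(base)$sensor_id))
    noise <- generate_noise_events(real, global_fraction = global_fraction,
                                   seed = derive_seed(seed, 20 + i))
    merged <- merge_streams(real, noise)
    fp <- count_false_positives(merged, score, detector)
    ctx <- detection_context(real, noise, score, detector)
    trials <- lapply(te, function(x) run_trial(ctx, x))
    results[[lev]] <- list(level = lev, certainties = certs, fp = fp,
                           detection = make_eval_report(trials_to_frame(trials)))
  }
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(level = r$level, n_fp = r$fp$n_fp, fp_per_day = r$fp$fp_per_day,
               n_detected = r$detection$n_detected,
               n_censored = r$detection$n_censored,
               n_excluded = r$detection$n_excluded,
               mean_delta = r$detection$mean_delta,
               median_delta = r$detection$median_delta,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(levels = results, summary = summary, te = te),
            class = "noise_level_study")
}

#' @export
print.noise_level_study <- function(x, ...) {
  cat("<noise_level_study>\n")
  print(x$summary)
  invisible(x)
}
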