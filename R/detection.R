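# Adaptive alarm thresholds from historical Inactivity Scores, and alarm
# onset detection.  Thresholds are weekend-aware (weekday queries reference
# weekday history only), outlier-clipped via the interquartile range, and
# scaled by a safety factor alpha.

#' Detector configuration
#'
#' @param psi_days Reference look-back in days (default 70): candidate
#'   reference times are drawn from `t - psi_days` days to `t - 1` day.
#' @param beta Half-width in seconds of the window around each reference time
#'   whose maximum score is taken (default 1 hour).
#' @param alpha Threshold scaling factor >= 1-ish (default 2), allowing scores
#'   some head-room beyond the historical maxima before alarming.
#' @param init_period Initialization period in seconds (default 10 weeks):
#'   thresholds are undefined — and alarms impossible — while the score
#'   history is shorter than this.
#' @param min_references Minimum number of usable reference times for a
#'   defined threshold (default 5); quartiles on fewer points are meaningless.
#' @param quantile_type Percentile convention passed to [stats::quantile()]
#'   (default 7: linear interpolation between order statistics).
#' @return A list of class `"detector_config"`.
#' @export
detector_config <- function(psi_days = 70, beta = 3600, alpha = 2.0,
                            init_period = 70 * 86400, min_references = 5,
                            quantile_type = 7) {
  stopifnot(psi_days > 1, beta > 0, alpha > 0, init_period >= 0,
            min_references >= 1)
  structure(list(psi_days = as.integer(psi_days), beta = as.numeric(beta),
                 alpha = as.numeric(alpha), init_period = as.numeric(init_period),
                 min_references = as.integer(min_references),
                 quantile_type = as.integer(quantile_type)),
            class = "detector_config")
}

#' Reference times for a threshold query
#'
#' One candidate per calendar day in `[t - psi_days, t - 1 day]`, at the same
#' clock time as `t`, kept iff its weekend status (Saturday/Sunday) matches
#' that of `t`.  Daily rhythms differ between weekdays and weekends, so the
#' two populations are never mixed.
#'
#' @param t Query time (`POSIXct`).
#' @param psi_days Look-back horizon in days.
#' @return Ascending `POSIXct` vector (50 weekday or 20 weekend references for
#'   `psi_days = 70` once full history is available).
#' @export
reference_times <- function(t, psi_days = 70) {
  t <- as_time(t)
  stopifnot(length(t) == 1, psi_days > 1)
  cand <- t - (1:psi_days) * 86400
  sort(cand[is_weekend(cand) == is_weekend(t)])
}

#' Windowed maxima of a score history around reference times
#'
#' For each reference time, the maximum score over the closed grid window
#' `[ref - beta, ref + beta]`.  Windows are clipped to the history's grid and,
#' when `query_time` is given, to grid points strictly before it (no
#' lookahead).  References whose window is empty after clipping are dropped.
#'
#' @param history A `score_series`.
#' @param refs `POSIXct` reference times (non-empty).
#' @param beta Window half-width in seconds.
#' @param query_time Optional causality cut-off.
#' @return Numeric maxima, one per surviving reference.
#' @export
window_maxima <- function(history, refs, beta, query_time = NULL) {
  stopifnot(inherits(history, "score_series"), beta > 0)
  if (length(refs) == 0) stopf("no reference times supplied")
  t0 <- secs(attr(history, "start"))
  step <- attr(history, "step")
  n <- nrow(history)
  k_cut <- if (is.null(query_time)) n - 1 else {
    m <- (secs(as_time(query_time)) - t0) / step
    ceiling(m - 1e-9) - 1 # grid points strictly before the query
  }
  r <- secs(as_time(refs))
  out <- vapply(r, function(ref) {
    lo <- max(ceiling((ref - beta - t0) / step - 1e-9), 0)
    hi <- min(floor((ref + beta - t0) / step + 1e-9), n - 1, k_cut)
    if (lo > hi) return(NA_real_)
    max(history$value[(lo:hi) + 1])
  }, numeric(1))
  out <- out[!is.na(out)]
  if (!length(out)) stopf("no reference window overlaps the score history")
  out
}

#' IQR-based upper bound for threshold clipping
#'
#' `Theta = Q3 + 1.5 * IQR`, the classical boxplot whisker, used to clip
#' outlier maxima (e.g. a one-off trip away from home) out of the threshold.
#'
#' @param values Numeric historical window maxima (non-empty).
#' @param type Percentile convention for [stats::quantile()].
#' @return The scalar bound `Theta`.
#' @export
#' @examples
#' iqr_upper_bound(c(1, 2, 3, 4)) # Q1=1.75, Q3=3.25 -> 5.5
iqr_upper_bound <- function(values, type = 7) {
  if (!length(values)) stopf("cannot compute an IQR bound from no values")
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  q[2] + 1.5 * (q[2] - q[1])
}

# Type-7 quartiles of an already sorted vector; avoids stats::quantile
# overhead in the per-grid-point threshold loop.
quartiles_t7 <- function(sv) {
  m <- length(sv)
  q_at <- function(p) {
    h <- (m - 1) * p
    lo <- floor(h)
    hi <- min(lo + 1, m - 1)
    sv[lo + 1] + (h - lo) * (sv[hi + 1] - sv[lo + 1])
  }
  c(q_at(0.25), q_at(0.75))
}

#' Threshold at a single query time
#'
#' The alarm threshold is `min(max(ISmax), Theta) * alpha`, where `ISmax` are
#' the windowed maxima of the score history at weekend-matched reference
#' times over the past `psi_days` days and `Theta` their IQR upper bound
#' ([iqr_upper_bound()]).  The threshold is undefined (`NA`) while `t` lies
#' within the initialization period of the history start, or when fewer than
#' `min_references` reference times have usable history; alarms are never
#' raised at undefined thresholds.
#'
#' @param history A `score_series` (scores up to at least `t`; only grid
#'   points strictly before `t` are consulted).
#' @param t Query time on the history grid.
#' @param config A [detector_config()].
#' @return The threshold, or `NA_real_` when undefined.
#' @export
compute_threshold <- function(history, t, config = detector_config()) {
  stopifnot(inherits(history, "score_series"), inherits(config, "detector_config"))
  t <- as_time(t)
  t0 <- attr(history, "start")
  if (secs(t) - secs(t0) < config$init_period) return(NA_real_)
  refs <- reference_times(t, config$psi_days)
  refs <- refs[refs >= t0] # a reference must itself lie on the history grid
  if (length(refs) < config$min_references) return(NA_real_)
  vals <- window_maxima(history, refs, config$beta, query_time = t)
  if (length(vals) < config$min_references) return(NA_real_)
  min(max(vals), iqr_upper_bound(vals, config$quantile_type)) * config$alpha
}

# ---- vectorized fast path ---------------------------------------------------

# Sliding-window maximum over [i - w, i + w] grid points, edges clipped.
slide_max <- function(x, w) {
  n <- length(x)
  out <- x
  if (w < 1 || n < 2) return(out)
  for (s in seq_len(min(w, n - 1))) {
    head_idx <- seq_len(n - s)
    out[head_idx] <- pmax(out[head_idx], x[head_idx + s])
    out[head_idx + s] <- pmax(out[head_idx + s], x[head_idx])
  }
  out
}

# Threshold computation against a windowed-max lookup.  `get_W` maps 0-based
# grid indices to windowed maxima, `n` is the number of known grid points,
# query_k are 0-based grid indices.  Assumes the step divides one day and
# beta + step <= 1 day, so reference windows can never reach the query time
# (causality holds without explicit clipping).
threshold_engine <- function(get_W, n, t0, step, config, query_k) {
  spd <- 86400 / step
  offs <- lapply(0:6, function(wd) {
    d <- 1:config$psi_days
    d[is_weekend_day((wd - d) %% 7) == is_weekend_day(wd)] * spd
  })
  wd_q <- (floor((t0 + query_k * step) / 86400) + 4) %% 7
  tp <- config$quantile_type
  minref <- config$min_references
  alpha <- config$alpha
  init <- config$init_period
  vapply(seq_along(query_k), function(i) {
    k <- query_k[i]
    if (k * step < init) return(NA_real_)
    js <- k - offs[[wd_q[i] + 1]]
    js <- js[js >= 0 & js < n]
    m <- length(js)
    if (m < minref) return(NA_real_)
    sv <- sort.int(get_W(js), method = "quick")
    q <- if (tp == 7) quartiles_t7(sv) else
      stats::quantile(sv, c(0.25, 0.75), type = tp, names = FALSE)
    theta <- q[2] + 1.5 * (q[2] - q[1])
    min(sv[m], theta) * alpha
  }, numeric(1))
}

#' Threshold series over a whole score history
#'
#' Computes [compute_threshold()] at every grid point (or a subset), using a
#' vectorized path when the grid step divides one day and `beta` is below one
#' day; otherwise it falls back to the per-point computation.
#'
#' @param history A `score_series`.
#' @param config A [detector_config()].
#' @param at Optional `POSIXct` subset of grid times to evaluate.
#' @return A `data.frame` with columns `time` and `threshold` (`NA` where
#'   undefined).
#' @export
threshold_series <- function(history, config = detector_config(), at = NULL) {
  stopifnot(inherits(history, "score_series"))
  t0 <- secs(attr(history, "start"))
  step <- attr(history, "step")
  if (is.null(at)) {
    query_k <- seq_len(nrow(history)) - 1
    times <- history$time
  } else {
    at <- as_time(at)
    query_k <- round((secs(at) - t0) / step)
    if (any(abs(secs(at) - (t0 + query_k * step)) > 1e-6)) {
      stopf("query times must lie on the history grid")
    }
    times <- at
  }
  fast <- abs(86400 / step - round(86400 / step)) < 1e-9 &&
    (config$beta + step) <= 86400
  if (fast) {
    W <- slide_max(history$value, round(config$beta / step))
    thr <- threshold_engine(function(js) W[js + 1], length(W),
                            t0, step, config, query_k)
  } else {
    thr <- vapply(times, function(tt) compute_threshold(history, tt, config),
                  numeric(1))
  }
  data.frame(time = times, threshold = thr)
}

#' Detect alarm onsets in a score series
#'
#' An alarm onset is a grid point whose score exceeds its threshold while the
#' previous grid point did not exceed its own: a prolonged excursion above the
#' threshold yields exactly one onset.  Grid points with undefined thresholds
#' never alarm (and count as "not above" for the following point).
#'
#' @param scores A `score_series` (typically kind `"IS"`).
#' @param config A [detector_config()].
#' @return A `data.frame` with one row per onset: `timestamp`, `score`,
#'   `threshold`.
#' @export
detect_alarm_onsets <- function(scores, config = detector_config()) {
  ths <- threshold_series(scores, config)
  v <- scores$value
  above <- !is.na(ths$threshold) & v > ths$threshold
  onset <- above & !c(FALSE, above[-length(above)])
  data.frame(timestamp = scores$time[onset], score = v[onset],
             threshold = ths$threshold[onset])
}
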