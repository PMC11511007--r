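# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded simulation helpers do not disturb the
#' caller's random-number stream.  A `NULL` seed evaluates `expr` as-is.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a RNG state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and a stream index.
derive_seed <- function(seed, index) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.double(seed) * 7919 + 104729 * index) %% 2147483587)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# POSIXct in a fixed zone: event times are naive local clock times; UTC keeps
# day arithmetic free of DST jumps.
iss_tz <- "UTC"

as_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(x)
  }
  out <- as.POSIXct(x, tz = iss_tz)
  if (anyNA(out)) stopf("unparseable timestamp(s): %s", paste(utils::head(x[is.na(out)], 3L), collapse = ", "))
  out
}

secs <- function(x) as.numeric(x) # POSIXct -> seconds since epoch

from_secs <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = iss_tz)

# Day-of-week 0..6 (Sunday = 0) for a POSIXct vector, via epoch-day arithmetic
# (1970-01-01 was a Thursday).  Avoids per-element POSIXlt conversion.
day_of_week <- function(t) {
  (floor(secs(t) / 86400) + 4) %% 7
}

is_weekend_day <- function(wday) wday == 0 | wday == 6

#' Is a time on a weekend?
#'
#' Saturday and Sunday count as weekend; used for reference-time matching in
#' threshold construction.
#'
#' @param t A `POSIXct` vector.
#' @return Logical vector.
#' @export
#' @examples
#' is_weekend(as.POSIXct("2024-01-06", tz = "UTC")) # Saturday
is_weekend <- function(t) {
  is_weekend_day(day_of_week(as_time(t)))
}
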