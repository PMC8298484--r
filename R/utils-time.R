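## Clock-time helpers. All internal clock arithmetic is done on decimal hours;
## POSIXct values are interpreted in UTC (the recordings carry no DST semantics).

#' Decimal clock hours of a timestamp
#'
#' @param x a `POSIXct` vector.
#' @return numeric vector of hours after midnight in `[0, 24)`.
#' @keywords internal
clockHours <- function(x) {
  lt <- as.POSIXlt(x, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Format decimal hours as hh:mm
#'
#' @param h numeric hours (any real; reduced modulo 24).
#' @return character vector `"hh:mm"`; `NA` stays `NA`.
#' @export
formatClock <- function(h) {
  out <- rep(NA_character_, length(h))
  ok <- !is.na(h)
  hh <- h[ok] %% 24
  mins <- round(hh * 60)
  mins <- mins %% (24 * 60)
  out[ok] <- sprintf("%02d:%02d", mins %/% 60, mins %% 60)
  out
}

#' Parse hh:mm to decimal hours
#' @param x character `"hh:mm"` or `"hh:mm:ss"`.
#' @return numeric hours.
#' @export
parseClock <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    p[1] + p[2] / 60 + if (length(p) > 2) p[3] / 3600 else 0
  }, numeric(1))
}

#' Circular mean of clock times
#'
#' Mean direction of clock times on a circle of the given period, mapped back
#' to `[0, period)`. Used for per-cycle observed extrema, where naive averaging
#' of times near midnight would be off by half a day.
#'
#' @param h numeric clock hours.
#' @param period circle length in hours (24 for clock time).
#' @return numeric scalar in `[0, period)`; `NA` if `h` is empty.
#' @export
circularMeanClock <- function(h, period = 24) {
  h <- h[!is.na(h)]
  if (length(h) == 0L) return(NA_real_)
  a <- 2 * pi * h / period
  m <- atan2(mean(sin(a)), mean(cos(a)))
  (m * period / (2 * pi)) %% period
}

#' Hours since an anchor clock time
#'
#' Unwraps clock hours onto a linear scale starting at the anchor, so ordinary
#' means and SDs are valid for night-time events that never occur near the
#' anchor (default 18:00 for sleep variables).
#'
#' @param h clock hours in `[0, 24)`.
#' @param anchor anchor clock hour.
#' @return hours since the anchor, in `[0, 24)`.
#' @export
hoursSinceAnchor <- function(h, anchor = 18) {
  (h - anchor) %% 24
}

#' Map anchored hours back to clock time
#' @param u hours since the anchor.
#' @param anchor anchor clock hour.
#' @return clock hours in `[0, 24)`.
#' @export
anchorToClock <- function(u, anchor = 18) {
  (u + anchor) %% 24
}

## a seed is valid if it is a single finite number representable as an integer
checkSeed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || !is.finite(seed) ||
      seed != round(seed) || abs(seed) >= 2^31) {
    stop("'seed' must be a single finite integer below 2^31", call. = FALSE)
  }
  as.integer(seed)
}

## derive a stream of child seeds from one master seed
deriveSeeds <- function(seed, n) {
  seed <- checkSeed(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}
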