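# small shared helpers: clock arithmetic, rounding, distances

#' Parse clock times to seconds since service-day midnight
#'
#' Accepts `"HH:MM"` or `"HH:MM:SS"` strings (hours may exceed 23 for
#' service days running past midnight) or numeric seconds, which are passed
#' through unchanged.
#'
#' @param x Character vector of clock strings, or numeric seconds.
#' @return Integer seconds since 00:00 of the service day.
#' @export
#' @examples
#' parse_clock("07:00")
#' parse_clock("11:30:15")
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.integer(round(x)))
  stopifnot(is.character(x))
  vapply(x, function(s) {
    parts <- suppressWarnings(as.integer(strsplit(s, ":", fixed = TRUE)[[1]]))
    if (length(parts) < 2L || length(parts) > 3L || anyNA(parts)) {
      stop("cannot parse clock time: '", s, "'", call. = FALSE)
    }
    if (length(parts) == 2L) parts <- c(parts, 0L)
    parts[[1L]] * 3600L + parts[[2L]] * 60L + parts[[3L]]
  }, integer(1), USE.NAMES = FALSE)
}

#' Format seconds since midnight as HH:MM:SS
#'
#' @param s Integer seconds since 00:00.
#' @return Character vector `"HH:MM:SS"`.
#' @export
format_clock <- function(s) {
  s <- as.integer(round(s))
  sprintf("%02d:%02d:%02d", s %/% 3600L, (s %% 3600L) %/% 60L, s %% 60L)
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for the published percentage
#' columns; `base::round()` rounds half to even and would disagree on exact
#' .5 remainders.
#'
#' @param x Numeric vector (non-negative values expected for percentages).
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)      # 1, where round(0.5) == 0
#' round_half_up(23.45, 1) # 23.5
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share of a count
#'
#' @param n Count (numerator).
#' @param total Total (denominator).
#' @param digits Decimal digits for half-up rounding; `NULL` for the exact
#'   value.
#' @return Percentage on the 0--100 scale.
#' @export
#' @examples
#' share_pct(191662, 239102)      # 80.2
#' share_pct(8973, 239102)        # 3.8
share_pct <- function(n, total, digits = 1) {
  stopifnot(total > 0)
  p <- 100 * n / total
  if (is.null(digits)) p else round_half_up(p, digits)
}

euclid <- function(x1, y1, x2, y2) {
  sqrt((x1 - x2)^2 + (y1 - y2)^2)
}

# nearest point in (px, py) for each row of (x, y); returns index and distance
nearest_point <- function(x, y, px, py) {
  idx <- integer(length(x))
  d <- numeric(length(x))
  for (i in seq_along(x)) {
    dd <- (px - x[i])^2 + (py - y[i])^2
    j <- which.min(dd)
    idx[i] <- j
    d[i] <- sqrt(dd[j])
  }
  list(index = idx, dist = d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
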