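# Internal numeric / date helpers shared across modules.

# Round half away from zero (printed tables use conventional rounding, not
# banker's). Small epsilon guards against values sitting a ULP below .5.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Format a percentage/statistic to `digits` decimals, trimming trailing zeros
# so 97.00 prints as "97" and 66.96 stays "66.96".
fmt_trim <- function(x, digits = 2) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    if (is.na(x[i])) { out[i] <- NA_character_; next }
    s <- formatC(round_half_up(x[i], digits), format = "f", digits = digits)
    s <- sub("0+$", "", s)
    out[i] <- sub("\\.$", "", s)
  }
  out
}

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  ifelse(month == 2L & leap, 29L, base)
}

#' Subtract calendar months from dates
#'
#' Calendar-month subtraction keeping the day of month, clamped to the last
#' day of the target month (2014-03-31 minus 1 month is 2014-02-28). Used to
#' anchor the closed 12-month ascertainment window at the interview date.
#'
#' @param dates a `Date` vector.
#' @param n number of months to subtract (non-negative integer).
#' @return a `Date` vector of the same length.
#' @examples
#' subtract_months(as.Date("2014-03-31"), 12)
#' @export
subtract_months <- function(dates, n) {
  stopifnot(inherits(dates, "Date"), length(n) == 1, n >= 0)
  lt <- as.POSIXlt(dates)
  mon0 <- lt$year * 12L + lt$mon - as.integer(n)   # months since 1900-01
  y <- mon0 %/% 12L + 1900L
  m <- mon0 %% 12L + 1L
  day <- pmin(lt$mday, days_in_month(y, m))
  out <- as.Date(sprintf("%04d-%02d-%02d", y, m, day))
  out[is.na(dates)] <- as.Date(NA)
  out
}

# Uniform random dates in [from, to], inclusive.
random_dates <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  stopifnot(to >= from)
  span <- as.integer(to - from) + 1L
  from + (floor(stats::runif(n) * span))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(..., log_file = NULL) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
  message(msg)
  if (!is.null(log_file)) cat(msg, "\n", file = log_file, append = TRUE, sep = "")
}
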