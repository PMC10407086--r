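# Time and formatting helpers shared across the package. All timestamps are
# naive wall-clock time at minute resolution, stored as POSIXct in UTC so that
# no daylight-saving arithmetic is ever applied.

#' Parse visit-log timestamps
#'
#' Timestamps in visit logs are ISO-8601 at minute resolution
#' (`"YYYY-MM-DD HH:MM"`), interpreted as naive wall-clock time.
#'
#' @param x Character vector of timestamps; empty strings and `NA` give `NA`.
#' @return POSIXct vector (UTC).
#' @export
parse_ts <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  as.POSIXct(x, format = "%Y-%m-%d %H:%M", tz = "UTC")
}

#' Format timestamps for visit logs
#'
#' @param x POSIXct vector.
#' @return Character vector `"YYYY-MM-DD HH:MM"`, `""` for `NA`.
#' @export
fmt_ts <- function(x) {
  out <- format(x, "%Y-%m-%d %H:%M", tz = "UTC")
  out[is.na(x)] <- ""
  out
}

#' Floor a timestamp to the clock hour
#'
#' @param x POSIXct vector.
#' @return POSIXct vector on the hour.
#' @export
floor_hour <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 3600) * 3600,
             origin = "1970-01-01", tz = "UTC")
}

#' Format a duration in hours as HH:MM
#'
#' Length-of-stay summaries are conventionally printed as zero-padded
#' hours:minutes (e.g. 4.3 h -> `"04:18"`). Durations are rounded to the
#' nearest minute; hours beyond 99 widen the field.
#'
#' @param hours Numeric vector of non-negative durations in hours.
#' @return Character vector `"HH:MM"`; `NA` stays `NA`.
#' @seealso [parse_hhmm()]
#' @export
fmt_hhmm <- function(hours) {
  m <- round(hours * 60)
  out <- sprintf("%02d:%02d", m %/% 60, m %% 60)
  out[is.na(hours)] <- NA_character_
  out
}

#' Parse an HH:MM duration back to hours
#'
#' Inverse of [fmt_hhmm()] at minute resolution:
#' `parse_hhmm(fmt_hhmm(x)) == x` whenever `x` is a whole number of minutes.
#'
#' @param x Character vector `"HH:MM"`.
#' @return Numeric hours.
#' @export
parse_hhmm <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L || anyNA(suppressWarnings(as.numeric(p))))
      return(NA_real_)
    as.numeric(p[1]) + as.numeric(p[2]) / 60
  }, numeric(1))
}

# Mortality percentage as printed in descriptive tables: 100 * deaths / n
# rounded to 2 decimals.
#' Unadjusted mortality percentage
#'
#' @param deaths Number of deaths.
#' @param n Group size.
#' @return `round(100 * deaths / n, 2)`; `NA` when `n` is 0.
#' @export
mortality_percent <- function(deaths, n) {
  ifelse(n > 0, round(100 * deaths / n, 2), NA_real_)
}

# internal: seconds-since-epoch numeric
.secs <- function(x) as.numeric(x)

# internal: deterministic sub-seed kept inside 32-bit integer range
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 104729 * as.numeric(k)) %% 2147483647)
}
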