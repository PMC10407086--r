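# Hourly crowding measurements. All window arithmetic is half-open
# [start, end): a patient departing exactly at t is not present at t, which
# prevents double counting at hour boundaries.

#' A half-open time window
#'
#' @param start,end POSIXct bounds; the window is `[start, end)` and `start`
#'   must precede `end`. All published computations use 1-hour windows, but
#'   any length is accepted.
#' @return An object of class `time_window`.
#' @export
time_window <- function(start, end) {
  if (!inherits(start, "POSIXct") || !inherits(end, "POSIXct"))
    stop("window bounds must be POSIXct")
  if (!(start < end)) stop("window start must precede end")
  structure(list(start = start, end = end), class = "time_window")
}

#' Presence time of visits within a window
#'
#' Length, in hours, of the overlap between each visit's presence interval
#' `[arrival_ts, departure_ts)` and a half-open window.
#'
#' @param visits Visit-log data frame.
#' @param window A [time_window()].
#' @return Numeric vector of hours in `[0, window length]`, one per visit.
#' @export
present_interval <- function(visits, window) {
  lo <- pmax(.secs(visits$arrival_ts), .secs(window$start))
  hi <- pmin(.secs(visits$departure_ts), .secs(window$end))
  pmax(hi - lo, 0) / 3600
}

#' ED census during a window
#'
#' Number of distinct visits at one ED present at any moment of the window
#' (positive overlap under the half-open convention).
#'
#' @param visits Visit-log data frame.
#' @param ed ED identifier.
#' @param window A [time_window()].
#' @return Integer count.
#' @export
census_during <- function(visits, ed, window) {
  v <- visits[visits$ed_id == ed, , drop = FALSE]
  sum(present_interval(v, window) > 0)
}

#' Patient-hours during a window
#'
#' Sum of the time all patients spent in the ED during the window, divided by
#' that window's census. With 1-hour windows the result lies in `(0, 1]`;
#' it is absent (`NA`) when the census is zero.
#'
#' @inheritParams census_during
#' @return Numeric fraction, or `NA` when no patient was present.
#' @export
patient_hours <- function(visits, ed, window) {
  v <- visits[visits$ed_id == ed, , drop = FALSE]
  pres <- present_interval(v, window)
  n <- sum(pres > 0)
  if (n == 0L) return(NA_real_)
  sum(pres) / n
}

#' Time to physician during a window
#'
#' Mean realized wait, in hours, from registration to first physician
#' contact, over patients who were waiting for a physician at some moment of
#' the window (waiting interval `[arrival_ts, physician_ts)` overlaps the
#' window). Patients never seen by a physician are excluded. Absent (`NA`)
#' when nobody qualifies.
#'
#' @inheritParams census_during
#' @return Numeric hours, or `NA`.
#' @export
time_to_physician <- function(visits, ed, window) {
  v <- visits[visits$ed_id == ed & !is.na(visits$physician_ts), ,
              drop = FALSE]
  if (!nrow(v)) return(NA_real_)
  lo <- pmax(.secs(v$arrival_ts), .secs(window$start))
  hi <- pmin(.secs(v$physician_ts), .secs(window$end))
  qual <- hi - lo > 0
  if (!any(qual)) return(NA_real_)
  mean((.secs(v$physician_ts) - .secs(v$arrival_ts))[qual]) / 3600
}

#' The mSEAL workload score
#'
#' Linear workload score combining patient-hours and time-to-physician:
#' `1.485 + 9.715 * patient_hours + 0.177 * time_to_physician`, describing
#' crowding from 1 (none) to 6 (extreme). Because the linear form can exceed
#' 6 the result is truncated into `[1, 6]` by default; set `clamp = FALSE`
#' for the raw score (used e.g. when building empirical percentiles, where
#' censoring at 6 would collapse the upper tail).
#'
#' @param ph Patient-hours fraction(s), `>= 0`.
#' @param ttp Time-to-physician in hours, `>= 0`.
#' @param clamp Truncate into `[1, 6]`? Default `TRUE`.
#' @return Numeric score(s); `NA` inputs give `NA`.
#' @export
mseal_score <- function(ph, ttp, clamp = TRUE) {
  if (any(ph < 0, na.rm = TRUE) || any(ttp < 0, na.rm = TRUE))
    stop("patient-hours and time-to-physician must be non-negative")
  s <- 1.485 + 9.715 * ph + 0.177 * ttp
  if (clamp) s <- pmin(pmax(s, 1), 6)
  s
}

#' Occupancy rate at an instant
#'
#' Number of patients present at one ED at time `t` (arrival inclusive,
#' departure exclusive) divided by its treatment beds.
#'
#' @param visits Visit-log data frame.
#' @param ed ED identifier.
#' @param t POSIXct instant.
#' @param beds Number of treatment beds, `> 0`.
#' @return Numeric ratio `>= 0` (can exceed 1 under crowding).
#' @export
occupancy_at <- function(visits, ed, t, beds) {
  if (!is.numeric(beds) || length(beds) != 1L || is.na(beds) || beds <= 0)
    stop("beds must be a single positive count")
  v <- visits[visits$ed_id == ed, , drop = FALSE]
  sum(.secs(v$arrival_ts) <= .secs(t) & .secs(t) < .secs(v$departure_ts)) /
    beds
}

#' Hourly crowding metric series
#'
#' For every ED and every clock hour `H` of the period, computes the
#' measurements of the most recent completed hour `[H - 1h, H)`: census,
#' patient-hours, time-to-physician and the mSEAL score (absent whenever
#' patient-hours or time-to-physician is absent, e.g. hours with few patients
#' or nobody waiting), plus the occupancy rate at the instant `H`. A visit
#' arriving during `[H, H + 1h)` is exposed to the row with `hour_start = H`.
#'
#' @param visits Visit-log data frame.
#' @param beds Named numeric vector of treatment beds per `ed_id`; every ED
#'   appearing in `visits` must be covered.
#' @param period Optional [time_window()] with bounds on the hour; default
#'   spans the arrival hours present in `visits`.
#' @param clamp_mseal Truncate scores into `[1, 6]`? Default `FALSE`: the
#'   series keeps the raw linear score so that empirical percentile exposure
#'   thresholds remain well defined when the raw score exceeds 6 (see the
#'   package vignette); clamping is available for presentation.
#' @return Data frame with columns `ed_id`, `hour_start` (POSIXct),
#'   `census`, `patient_hours`, `time_to_physician`, `mseal`,
#'   `occupancy_rate`, `beds`; absent measurements are `NA`.
#' @export
hourly_metrics <- function(visits, beds, period = NULL, clamp_mseal = FALSE) {
  eds <- sort(unique(visits$ed_id))
  uncovered <- setdiff(eds, names(beds))
  if (length(uncovered))
    stop("no bed count configured for ED(s): ",
         paste(uncovered, collapse = ", "))
  if (is.null(period)) {
    if (!nrow(visits)) stop("empty visit log and no explicit period")
    period <- time_window(floor_hour(min(visits$arrival_ts)),
                          floor_hour(max(visits$arrival_ts)) + 3600)
  }
  h0 <- .secs(period$start)
  hend <- .secs(period$end)
  if (h0 %% 3600 != 0 || hend %% 3600 != 0)
    stop("period boundaries must fall on the hour")
  nh <- as.integer((hend - h0) / 3600)
  hours <- h0 + 3600 * (seq_len(nh) - 1)   # row k: H = hours[k]
  if (!length(eds)) eds <- names(beds)
  out <- lapply(eds, function(ed) {
    v <- visits[visits$ed_id == ed, , drop = FALSE]
    arr <- .secs(v$arrival_ts)
    dep <- .secs(v$departure_ts)
    # windows indexed by k: [hours[k] - 3600, hours[k])
    spread <- function(lo, hi, val) {
      # distribute interval [lo, hi) over hour windows; returns per-window
      # overlap sums, counts and value sums
      sums <- numeric(nh); cnts <- integer(nh); vals <- numeric(nh)
      ok <- hi > lo
      lo <- lo[ok]; hi <- hi[ok]; val <- val[ok]
      if (length(lo)) {
        k1 <- pmax(as.integer((3600 * floor(lo / 3600) - h0) / 3600) + 2L, 1L)
        k2 <- pmin(as.integer((3600 * floor((hi - 1) / 3600) - h0) / 3600) + 2L,
                   nh)
        keep <- k2 >= k1
        if (any(keep)) {
          nrep <- k2[keep] - k1[keep] + 1L
          idx <- rep(which(keep), nrep)
          kk <- rep(k1[keep], nrep) + sequence(nrep) - 1L
          ws <- h0 + 3600 * (kk - 2)   # window start of row kk
          ov <- pmin(hi[idx], ws + 3600) - pmax(lo[idx], ws)
          agg <- rowsum(cbind(ov, val[idx], 1), kk)
          at <- as.integer(rownames(agg))
          sums[at] <- agg[, 1]
          vals[at] <- agg[, 2]
          cnts[at] <- agg[, 3]
        }
      }
      list(sum = sums, val = vals, n = cnts)
    }
    pres <- spread(arr, dep, numeric(length(arr)))
    census <- pres$n
    ph <- ifelse(census > 0, pres$sum / 3600 / census, NA_real_)
    seen <- !is.na(v$physician_ts)
    wait_h <- (.secs(v$physician_ts)[seen] - arr[seen]) / 3600
    wt <- spread(arr[seen], .secs(v$physician_ts)[seen], wait_h)
    ttp <- ifelse(wt$n > 0, wt$val / wt$n, NA_real_)
    occ <- (findInterval(hours, sort(arr)) - findInterval(hours, sort(dep))) /
      beds[[ed]]
    ms <- ifelse(is.na(ph) | is.na(ttp), NA_real_,
                 1.485 + 9.715 * ph + 0.177 * ttp)
    if (clamp_mseal) ms <- pmin(pmax(ms, 1), 6)
    data.frame(
      ed_id = ed,
      hour_start = as.POSIXct(hours, origin = "1970-01-01", tz = "UTC"),
      census = census,
      patient_hours = ph,
      time_to_physician = ttp,
      mseal = ms,
      occupancy_rate = occ,
      beds = beds[[ed]],
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an hourly metric series as delimited text
#'
#' @param metrics Output of [hourly_metrics()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly. Absent values are written as empty fields.
#' @export
write_metrics <- function(metrics, path, delim = ",") {
  out <- metrics
  out$hour_start <- fmt_ts(out$hour_start)
  utils::write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read an hourly metric series written by [write_metrics()]
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return Metric series data frame.
#' @export
read_metrics <- function(path, delim = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, na.strings = "")
  raw$hour_start <- parse_ts(raw$hour_start)
  raw$ed_id <- as.character(raw$ed_id)
  raw
}
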