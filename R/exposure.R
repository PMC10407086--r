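# Exposure construction: ED- and hour-of-day-stratified empirical percentile
# thresholds, per-visit exposure categories and left truncation of repeat
# visits.

#' Exposure category levels
#'
#' Factor levels used for the crowding exposure: below the 85th percentile
#' (reference), 85-90, 90-95, above the 95th, and `MISSING` for visits
#' arriving at hours where the metric could not be computed.
#' @export
EXPOSURE_LEVELS <- c("REF_LT85", "Q85_90", "Q90_95", "GT95", "MISSING")

#' Stratified percentile exposure thresholds
#'
#' Computes, for every (ED, hour-of-day 0-23) stratum, the empirical 85th,
#' 90th and 95th percentiles of the non-absent values of a crowding metric,
#' using linear interpolation between order statistics
#' (`stats::quantile(type = 7)`). Stratification by ED and arrival hour
#' absorbs between-site baseline differences and intra-day cycles, making the
#' categories comparable across sites.
#'
#' @param metrics Hourly metric series from [hourly_metrics()].
#' @param metric `"mseal"` or `"occupancy"`.
#' @param min_stratum_n Strata with fewer non-absent values than this trigger
#'   a single collapsed warning (quantiles unstable); default 20.
#' @param warn Emit that warning? Default `TRUE`.
#' @return Data frame of class `exposure_thresholds` with columns `ed_id`,
#'   `hour` (0-23), `q85`, `q90`, `q95`, `n`; `attr(, "metric")` records the
#'   metric. `q85 <= q90 <= q95` holds in every stratum.
#' @export
compute_thresholds <- function(metrics, metric = c("mseal", "occupancy"),
                               min_stratum_n = 20, warn = TRUE) {
  metric <- match.arg(metric)
  col <- if (metric == "mseal") "mseal" else "occupancy_rate"
  vals <- metrics[[col]]
  hod <- as.integer(format(metrics$hour_start, "%H", tz = "UTC"))
  sep <- "\x1f"  # unit separator: cannot occur in an ED id
  key <- interaction(metrics$ed_id, hod, drop = TRUE, lex.order = TRUE,
                     sep = sep)
  ok <- !is.na(vals)
  qs <- vapply(split(vals[ok], key[ok]), stats::quantile,
               numeric(3), probs = c(0.85, 0.90, 0.95), names = FALSE,
               type = 7)
  strata <- do.call(rbind, strsplit(colnames(qs), sep, fixed = TRUE))
  out <- data.frame(
    ed_id = strata[, 1],
    hour = as.integer(strata[, 2]),
    q85 = qs[1, ],
    q90 = qs[2, ],
    q95 = qs[3, ],
    n = as.integer(table(key[ok])[colnames(qs)]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$ed_id, out$hour), , drop = FALSE]
  rownames(out) <- NULL
  small <- out$n < min_stratum_n
  if (warn && any(small))
    warning(sum(small), " stratum/strata with fewer than ", min_stratum_n,
            " observed hours; percentile thresholds there are unstable",
            call. = FALSE)
  attr(out, "metric") <- metric
  class(out) <- c("exposure_thresholds", "data.frame")
  out
}

# internal: bin metric values against stratum cutpoints; lower-inclusive so a
# value equal to a cutpoint goes to the higher-crowding bin
.bin_exposure <- function(vals, q85, q90, q95) {
  out <- rep(NA_character_, length(vals))
  ok <- !is.na(vals)
  out[ok] <- ifelse(vals[ok] < q85[ok], "REF_LT85",
             ifelse(vals[ok] < q90[ok], "Q85_90",
             ifelse(vals[ok] < q95[ok], "Q90_95", "GT95")))
  out[!ok] <- "MISSING"
  factor(out, levels = EXPOSURE_LEVELS)
}

#' Assign per-visit crowding exposure categories
#'
#' Looks up, for each visit, the metric value of the most recent completed
#' hour before arrival (the series row whose `hour_start` is the visit's
#' arrival hour) and bins it against the visit's (ED, hour-of-day) stratum
#' thresholds. Bins are lower-inclusive: a value equal to a cutpoint falls in
#' the higher-crowding bin. Visits whose arrival-hour metric is absent get
#' `MISSING`.
#'
#' @param visits Visit-log data frame.
#' @param metrics Hourly metric series covering all arrival hours.
#' @param thresholds Output of [compute_thresholds()].
#' @return Factor with levels [EXPOSURE_LEVELS], one per visit.
#' @export
assign_exposure <- function(visits, metrics, thresholds) {
  metric <- attr(thresholds, "metric")
  col <- if (identical(metric, "occupancy")) "occupancy_rate" else "mseal"
  vkey <- paste(visits$ed_id, .secs(floor_hour(visits$arrival_ts)))
  mkey <- paste(metrics$ed_id, .secs(metrics$hour_start))
  mrow <- match(vkey, mkey)
  if (anyNA(mrow))
    stop("metric series does not cover the arrival hour of ",
         sum(is.na(mrow)), " visit(s)")
  hod <- as.integer(format(visits$arrival_ts, "%H", tz = "UTC"))
  trow <- match(paste(visits$ed_id, hod),
                paste(thresholds$ed_id, thresholds$hour))
  if (anyNA(trow))
    stop("thresholds do not cover the (ED, hour-of-day) stratum of ",
         sum(is.na(trow)), " visit(s)")
  .bin_exposure(metrics[[col]][mrow], thresholds$q85[trow],
                thresholds$q90[trow], thresholds$q95[trow])
}

#' Left-truncate repeat visits
#'
#' Scanning each patient's visits in arrival order, retains a visit only if
#' no retained visit of the same patient arrived strictly within the
#' preceding `horizon_days` (a visit exactly `horizon_days` later starts a
#' new follow-up window and is retained). This removes follow-up overlap
#' caused by repeat visits; `horizon_days` should equal the mortality
#' follow-up of the model being fitted.
#'
#' @param visits Visit-log data frame.
#' @param horizon_days Positive follow-up horizon in days.
#' @return The retained visits, in the original row order.
#' @export
left_truncate <- function(visits, horizon_days) {
  if (!is.numeric(horizon_days) || horizon_days <= 0)
    stop("horizon_days must be positive")
  if (!nrow(visits)) return(visits)
  t_days <- .secs(visits$arrival_ts) / 86400
  ord <- order(visits$patient_id, t_days)
  keep <- logical(nrow(visits))
  pid <- visits$patient_id[ord]
  tt <- t_days[ord]
  grp_start <- which(!duplicated(pid))
  grp_end <- c(grp_start[-1] - 1L, length(pid))
  for (g in seq_along(grp_start)) {
    i0 <- grp_start[g]; i1 <- grp_end[g]
    last <- -Inf
    for (i in i0:i1) {
      if (tt[i] - last >= horizon_days || !is.finite(last)) {
        keep[ord[i]] <- TRUE
        last <- tt[i]
      }
    }
  }
  out <- visits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize exposure thresholds as JSON
#'
#' @param thresholds Output of [compute_thresholds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  obj <- list(
    metric = attr(thresholds, "metric"),
    strata = lapply(seq_len(nrow(thresholds)), function(i) list(
      ed = thresholds$ed_id[i], hour = thresholds$hour[i],
      q85 = thresholds$q85[i], q90 = thresholds$q90[i],
      q95 = thresholds$q95[i], n = thresholds$n[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read exposure thresholds written by [write_thresholds()]
#'
#' @param path JSON file path.
#' @return `exposure_thresholds` data frame.
#' @export
read_thresholds <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- obj$strata
  names(out)[names(out) == "ed"] <- "ed_id"
  out <- out[c("ed_id", "hour", "q85", "q90", "q95", "n")]
  out$hour <- as.integer(out$hour)
  out$n <- as.integer(out$n)
  attr(out, "metric") <- obj$metric
  class(out) <- c("exposure_thresholds", "data.frame")
  out
}
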