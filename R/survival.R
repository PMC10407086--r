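# Covariate encoding and Cox proportional-hazards estimation for 1-, 7- and
# 30-day all-cause mortality, plus the unadjusted descriptive tables.

.AGE_BANDS <- c("0-18", "19-39", "40-59", "60-79", "80+")

# internal: whole days from arrival date to death date (NA when no death)
.death_day <- function(visits) {
  as.integer(visits$death_date - as.Date(visits$arrival_ts, tz = "UTC"))
}

#' Chief-complaint categories by absolute 30-day mortality
#'
#' Ranks complaint codes by the absolute number of deaths within 30 days of
#' arrival among visits carrying that code (count, not rate) and keeps the
#' top `k` as their own categories; everything else maps to `"OTHER"`. Ties
#' at rank `k` are broken in favour of the lexicographically smaller code.
#'
#' @param visits Visit-log data frame (death dates resolved).
#' @param k Number of complaint categories to keep, default 10.
#' @return Named character vector mapping every observed complaint code to
#'   its category (itself or `"OTHER"`).
#' @export
top_complaints <- function(visits, k = 10) {
  codes <- sort(unique(visits$complaint))
  d <- .death_day(visits)
  dead30 <- !is.na(d) & d >= 0 & d < 30
  deaths <- table(factor(visits$complaint[dead30], levels = codes))
  ranked <- codes[order(-as.integer(deaths), codes)]
  kept <- utils::head(ranked, k)
  out <- ifelse(codes %in% kept, codes, "OTHER")
  stats::setNames(out, codes)
}

#' Encode analysis rows for survival modelling
#'
#' Turns cleaned, exposure-assigned visits into one analysis row per visit:
#' age banded (0-18, 19-39, 40-59, 60-79, 80+; age 80 falls in the oldest
#' band), RETTS acuity with the optional 5th category merged into 4 and then
#' inverted (`acuity_inv = 5 - min(acuity, 4)`, so 1 = lowest acuity =
#' reference), chief complaint mapped through `complaint_map` with `"OTHER"`
#' as reference, and the follow-up pair: with death registered at day
#' resolution, the event time is whole days since arrival plus a half-day
#' offset (avoiding zero-length survival times); a visit is an event iff the
#' death day is strictly within the horizon, otherwise it is censored at
#' `horizon_days`.
#'
#' @param visits Visit-log data frame with an `exposure` column (factor from
#'   [assign_exposure()]).
#' @param complaint_map Mapping from [top_complaints()].
#' @param horizon_days Follow-up horizon: 1, 7 or 30 days.
#' @return Data frame of analysis rows: `time`, `event`, `exposure`,
#'   `age_band`, `sex`, `ambulance`, `admitted`, `acuity_inv`,
#'   `complaint_cat`. Reference levels: `REF_LT85`, youngest age band,
#'   female, no ambulance, not admitted, `acuity_inv` 1, `OTHER`.
#' @export
encode_covariates <- function(visits, complaint_map, horizon_days) {
  if (is.null(visits$exposure))
    stop("visits must carry an 'exposure' column; see assign_exposure()")
  if (any(is.na(visits$age_years)) || any(visits$age_years < 0))
    stop("invalid age_years")
  if (!all(visits$acuity %in% 1:5)) stop("acuity outside 1-5")
  d <- .death_day(visits)
  event <- !is.na(d) & d >= 0 & d < horizon_days
  kept <- sort(setdiff(unique(complaint_map), "OTHER"))
  cat_of <- unname(complaint_map[visits$complaint])
  cat_of[is.na(cat_of)] <- "OTHER"
  data.frame(
    time = ifelse(event, d + 0.5, horizon_days),
    event = event,
    exposure = factor(visits$exposure, levels = EXPOSURE_LEVELS),
    age_band = cut(visits$age_years, c(-1, 18, 39, 59, 79, Inf),
                   labels = .AGE_BANDS),
    sex = factor(visits$sex, levels = c("female", "male")),
    ambulance = visits$ambulance,
    admitted = visits$admitted,
    acuity_inv = factor(5L - pmin(visits$acuity, 4L), levels = 1:4),
    complaint_cat = factor(cat_of, levels = c("OTHER", kept)),
    stringsAsFactors = FALSE
  )
}

#' Adjusted Cox proportional-hazards fit
#'
#' Fits a Cox proportional-hazards model for short-term mortality with the
#' crowding exposure (reference: below the 85th percentile) and the standard
#' ED case-mix adjustment — age band, sex, ambulance arrival, hospital
#' admission, inverted acuity and chief-complaint category — all as
#' categorical terms. Ties are handled with the Efron approximation (deaths
#' are day-resolution, so heavily tied); confidence intervals are 95% Wald
#' intervals on the hazard-ratio scale. Rows with `MISSING` exposure are
#' excluded before fitting. Adjustment covariates without contrast in the
#' data (a single observed level) are dropped from the formula; the fit is
#' invariant to row order.
#'
#' @param rows Analysis rows from [encode_covariates()].
#' @return Object of class `edcrowd_cox`: a list with `hr` (data frame of
#'   `level`, `hr`, `ci_low`, `ci_high` for each non-reference exposure
#'   level), `coefficients` (all model coefficients on the log-hazard
#'   scale), `n_rows`, `n_events` and `horizon` when available.
#' @export
fit_cox <- function(rows) {
  rows <- rows[!is.na(rows$exposure) & rows$exposure != "MISSING", ,
               drop = FALSE]
  rows$exposure <- droplevels(rows$exposure)
  if (!nrow(rows)) stop("no analysis rows after excluding MISSING exposure")
  if (sum(rows$event) < 1) stop("no events: cannot estimate mortality hazard")
  if (nlevels(rows$exposure) < 2)
    stop("degenerate design: no contrast in exposure")
  covs <- c("age_band", "sex", "ambulance", "admitted", "acuity_inv",
            "complaint_cat")
  use <- vapply(covs, function(cn) {
    x <- rows[[cn]]
    if (is.factor(x)) nlevels(droplevels(x)) > 1 else length(unique(x)) > 1
  }, logical(1))
  for (cn in covs[use]) if (is.factor(rows[[cn]]))
    rows[[cn]] <- droplevels(rows[[cn]])
  fml <- stats::reformulate(c("exposure", covs[use]),
                            response = "survival::Surv(time, event)")
  fit <- survival::coxph(fml, data = rows, ties = "efron")
  if (anyNA(stats::coef(fit)[grep("^exposure", names(stats::coef(fit)))]))
    stop("degenerate design: exposure effect inestimable")
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  is_exp <- grepl("^exposure", names(co))
  hr <- data.frame(
    level = sub("^exposure", "", names(co)[is_exp]),
    hr = exp(co[is_exp]),
    ci_low = exp(co[is_exp] - z * se[is_exp]),
    ci_high = exp(co[is_exp] + z * se[is_exp]),
    stringsAsFactors = FALSE
  )
  rownames(hr) <- NULL
  structure(list(hr = hr, coefficients = co, n_rows = nrow(rows),
                 n_events = sum(rows$event),
                 iter = fit$iter), class = "edcrowd_cox")
}

#' @export
print.edcrowd_cox <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit: %d rows, %d events\n",
              x$n_rows, x$n_events))
  cat("Hazard ratios vs REF_LT85 (95% CI):\n")
  for (i in seq_len(nrow(x$hr)))
    cat(sprintf("  %-8s %5.2f (%.2f-%.2f)\n", x$hr$level[i], x$hr$hr[i],
                x$hr$ci_low[i], x$hr$ci_high[i]))
  invisible(x)
}

#' Unadjusted outcome table by exposure category
#'
#' Per exposure category: visit count, deaths and mortality percentage at
#' each horizon (percent = 100 * deaths / n, rounded to 2 decimals), and
#' length-of-stay summaries (mean, SD, median, IQR) both in hours and
#' formatted `HH:MM`. Empty categories report `NA` fields.
#'
#' @param visits Visit-log data frame with an `exposure` column.
#' @param horizons Integer horizons in days, default `c(1, 7, 30)`.
#' @return Data frame of class `mortality_table`, one row per exposure
#'   category.
#' @export
mortality_table <- function(visits, horizons = c(1, 7, 30)) {
  expo <- factor(visits$exposure, levels = EXPOSURE_LEVELS)
  d <- .death_day(visits)
  los <- as.numeric(visits$departure_ts - visits$arrival_ts, units = "hours")
  out <- lapply(EXPOSURE_LEVELS, function(lv) {
    sel <- !is.na(expo) & expo == lv
    n <- sum(sel)
    row <- list(exposure = lv, n = n)
    for (h in horizons) {
      deaths <- sum(!is.na(d[sel]) & d[sel] >= 0 & d[sel] < h)
      row[[sprintf("deaths_%dd", h)]] <- if (n) deaths else NA_integer_
      row[[sprintf("mortality_%dd_pct", h)]] <-
        if (n) mortality_percent(deaths, n) else NA_real_
    }
    ls <- los[sel]
    row$los_mean <- if (n) mean(ls) else NA_real_
    row$los_sd <- if (n > 1) stats::sd(ls) else NA_real_
    row$los_median <- if (n) stats::median(ls) else NA_real_
    row$los_q1 <- if (n) unname(stats::quantile(ls, 0.25)) else NA_real_
    row$los_q3 <- if (n) unname(stats::quantile(ls, 0.75)) else NA_real_
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  for (cn in c("mean", "sd", "median", "q1", "q3"))
    res[[paste0("los_", cn, "_hhmm")]] <- fmt_hhmm(res[[paste0("los_", cn)]])
  class(res) <- c("mortality_table", "data.frame")
  res
}

#' Repeat visits among dying and surviving patients
#'
#' Among patients who died within `horizon_days` of one of their visits, and
#' among those who did not, the percentage having more than one visit within
#' `horizon_days` of an index visit (i.e. any two of their visits closer than
#' the horizon).
#'
#' @param visits Visit-log data frame.
#' @param horizon_days Follow-up horizon in days.
#' @return Named numeric vector `c(dying = ..., surviving = ...)` in percent;
#'   `NA` when a group is empty.
#' @export
repeat_visit_summary <- function(visits, horizon_days) {
  d <- .death_day(visits)
  died_visit <- !is.na(d) & d >= 0 & d < horizon_days
  t_days <- .secs(visits$arrival_ts) / 86400
  ord <- order(visits$patient_id, t_days)
  pid <- visits$patient_id[ord]
  tt <- t_days[ord]
  gap <- c(diff(tt), Inf)
  same <- c(pid[-1] == pid[-length(pid)], FALSE)
  close_pair <- same & gap < horizon_days
  pat_repeat <- tapply(close_pair, pid, any)
  pat_died <- tapply(died_visit[ord], pid, any)
  pct <- function(x) if (length(x)) 100 * mean(x) else NA_real_
  c(dying = pct(pat_repeat[pat_died]),
    surviving = pct(pat_repeat[!pat_died]))
}
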