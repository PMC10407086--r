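# Shared fixtures and independent oracles, built in code.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# quick visit-log builder with sensible defaults
mk_visits <- function(arrival, departure, physician = NA, ed = "A",
                      patient = NULL, age = 50, sex = "female",
                      ambulance = FALSE, admitted = FALSE, acuity = 3,
                      complaint = "OTH", death = NA) {
  n <- length(arrival)
  arrival <- ts(arrival)
  departure <- ts(departure)
  physician <- if (all(is.na(physician)))
    as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC")
  else ts(physician)
  if (is.null(patient)) patient <- sprintf("P%03d", seq_len(n))
  death <- if (all(is.na(death))) as.Date(rep(NA_integer_, n),
                                          origin = "1970-01-01")
  else as.Date(death)
  visit_log(
    visit_id = sprintf("V%03d", seq_len(n)),
    patient_id = rep_len(patient, n),
    ed_id = rep_len(ed, n),
    arrival_ts = arrival,
    physician_ts = physician,
    departure_ts = departure,
    age_years = rep_len(age, n),
    sex = rep_len(sex, n),
    ambulance = rep_len(ambulance, n),
    admitted = rep_len(admitted, n),
    acuity = rep_len(acuity, n),
    complaint = rep_len(complaint, n),
    death_date = rep_len(death, n)
  )
}

# random minute-resolution fixture around a base day
rand_visits <- function(n, ed = "A", base = "2017-03-01 00:00",
                        span_h = 12, max_los_min = 360) {
  arr <- as.numeric(ts(base)) + 60 * sample.int(span_h * 60, n,
                                                replace = TRUE)
  los <- 60 * sample.int(max_los_min, n, replace = TRUE)
  seen <- runif(n) < 0.8
  wait <- pmin(60 * sample.int(180, n, replace = TRUE), los)
  mk_visits(
    arrival = as.POSIXct(arr, origin = "1970-01-01", tz = "UTC"),
    departure = as.POSIXct(arr + los, origin = "1970-01-01", tz = "UTC"),
    physician = as.POSIXct(ifelse(seen, arr + wait, NA_real_),
                           origin = "1970-01-01", tz = "UTC"),
    ed = ed
  )
}

# --- 1-minute-grid brute-force oracles (independent of the interval code) ---

grid_minutes <- function(window) {
  seq(as.numeric(window$start), as.numeric(window$end) - 60, by = 60)
}

grid_present_minutes <- function(visits, ed, window) {
  v <- visits[visits$ed_id == ed, , drop = FALSE]
  mins <- grid_minutes(window)
  vapply(seq_len(nrow(v)), function(i) {
    sum(as.numeric(v$arrival_ts[i]) <= mins &
          mins < as.numeric(v$departure_ts[i]))
  }, numeric(1))
}

grid_census <- function(visits, ed, window) {
  sum(grid_present_minutes(visits, ed, window) > 0)
}

grid_patient_hours <- function(visits, ed, window) {
  pm <- grid_present_minutes(visits, ed, window)
  if (!any(pm > 0)) return(NA_real_)
  sum(pm) / 60 / sum(pm > 0)
}

grid_occupancy <- function(visits, ed, t, beds) {
  v <- visits[visits$ed_id == ed, , drop = FALSE]
  sum(as.numeric(v$arrival_ts) <= as.numeric(t) &
        as.numeric(t) < as.numeric(v$departure_ts)) / beds
}

beds_of <- function(cfg) stats::setNames(cfg$eds$beds, cfg$eds$ed_id)

# metric series built directly: one (ed, hour-of-day) stratum per call,
# values spread over successive days so each lands in the same stratum
mk_series <- function(values, ed = "A", hod = 9) {
  n <- length(values)
  data.frame(
    ed_id = ed,
    hour_start = ts("2017-01-01 00:00") + 86400 * (seq_len(n) - 1) +
      3600 * hod,
    census = 1L,
    patient_hours = 0.5,
    time_to_physician = 0.5,
    mseal = values,
    occupancy_rate = 0.5,
    beds = 10,
    stringsAsFactors = FALSE
  )
}

# full analysis on a simulated log: exposure + Cox at one horizon
pipeline_fit <- function(visits, beds, horizon) {
  m <- hourly_metrics(visits, beds)
  thr <- compute_thresholds(m, "mseal", warn = FALSE)
  visits$exposure <- assign_exposure(visits, m, thr)
  rows <- encode_covariates(visits, top_complaints(visits), horizon)
  fit_cox(rows)
}
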