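# Visit-log data model: read, validate, write and clean timestamped ED visit
# records. A visit log is a plain data.frame with one row per ED visit and the
# canonical columns below; all downstream functions take this shape.

.VISIT_COLUMNS <- c("visit_id", "patient_id", "ed_id",
                    "arrival_ts", "physician_ts", "departure_ts",
                    "age_years", "sex", "ambulance", "admitted",
                    "acuity", "complaint", "death_date")

.parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Construct a visit-log data frame
#'
#' Assembles and validates the canonical visit-log shape used throughout the
#' package: one row per ED visit with identifiers, timestamps (minute
#' resolution, naive wall-clock), demographics, RETTS acuity (1 = highest
#' urgency, optional category 5 = lowest), a chief-complaint code and an
#' optional date of death.
#'
#' @param visit_id,patient_id,ed_id Character identifiers.
#' @param arrival_ts,departure_ts POSIXct arrival/departure; arrival must
#'   precede departure.
#' @param physician_ts POSIXct first physician contact, `NA` when the patient
#'   was never seen; when present must lie in `[arrival_ts, departure_ts]`.
#' @param age_years Non-negative integer age.
#' @param sex `"female"` or `"male"`.
#' @param ambulance,admitted Logical flags.
#' @param acuity Integer 1-5.
#' @param complaint Chief-complaint code.
#' @param death_date `Date` of death or `NA`.
#' @return A `data.frame` with the canonical visit-log columns.
#' @export
visit_log <- function(visit_id, patient_id, ed_id, arrival_ts, physician_ts,
                      departure_ts, age_years, sex, ambulance, admitted,
                      acuity, complaint, death_date) {
  v <- data.frame(
    visit_id = as.character(visit_id),
    patient_id = as.character(patient_id),
    ed_id = as.character(ed_id),
    arrival_ts = arrival_ts,
    physician_ts = physician_ts,
    departure_ts = departure_ts,
    age_years = as.integer(age_years),
    sex = as.character(sex),
    ambulance = as.logical(ambulance),
    admitted = as.logical(admitted),
    acuity = as.integer(acuity),
    complaint = as.character(complaint),
    death_date = death_date,
    stringsAsFactors = FALSE
  )
  validate_visits(v)
  v
}

#' Validate a visit-log data frame
#'
#' Checks the canonical column set and the record invariants: arrival strictly
#' before departure; physician contact (when present) between arrival and
#' departure; acuity in 1-5; non-negative age; sex in \{female, male\}.
#'
#' @param visits Visit-log data frame.
#' @return `visits`, invisibly; errors on violation.
#' @export
validate_visits <- function(visits) {
  miss <- setdiff(.VISIT_COLUMNS, names(visits))
  if (length(miss))
    stop("visit log is missing columns: ", paste(miss, collapse = ", "))
  bad <- .visit_row_problems(visits)
  if (nrow(bad))
    stop("invalid visit records (first: row ", bad$row[1], ": ",
         bad$message[1], "); ", nrow(bad), " problem(s) in total")
  invisible(visits)
}

# internal: row-indexed invariant violations as a data.frame(row, message)
.visit_row_problems <- function(visits) {
  probs <- list()
  add <- function(idx, msg) {
    if (any(idx, na.rm = TRUE))
      probs[[length(probs) + 1L]] <<- data.frame(
        row = which(idx), message = msg, stringsAsFactors = FALSE)
  }
  add(is.na(visits$arrival_ts), "unparseable or missing arrival_ts")
  add(is.na(visits$departure_ts), "unparseable or missing departure_ts")
  ok_ts <- !is.na(visits$arrival_ts) & !is.na(visits$departure_ts)
  add(ok_ts & visits$arrival_ts >= visits$departure_ts,
      "departure_ts not after arrival_ts")
  has_phys <- !is.na(visits$physician_ts)
  add(has_phys & ok_ts & (visits$physician_ts < visits$arrival_ts |
                            visits$physician_ts > visits$departure_ts),
      "physician_ts outside [arrival_ts, departure_ts]")
  add(is.na(visits$age_years) | visits$age_years < 0L, "invalid age_years")
  add(!visits$sex %in% c("female", "male"), "sex not female/male")
  add(is.na(visits$ambulance), "invalid ambulance flag")
  add(is.na(visits$admitted), "invalid admitted flag")
  add(is.na(visits$acuity) | !visits$acuity %in% 1:5, "acuity outside 1-5")
  if (!length(probs))
    return(data.frame(row = integer(), message = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, probs)
  out[order(out$row), , drop = FALSE]
}

#' Read a delimited visit log
#'
#' Reads a delimited text file (header row required) into the canonical
#' visit-log shape. Timestamps are `"YYYY-MM-DD HH:MM"`, death dates
#' `"YYYY-MM-DD"`, empty string means absent. A *dialect* maps external column
#' names onto the canonical ones. Rows violating record invariants are
#' rejected, not silently dropped: they are returned as row-indexed
#' diagnostics in `attr(result, "diagnostics")`.
#'
#' @param path File path.
#' @param dialect Named character vector or list mapping canonical field names
#'   to the column names used in the file (e.g.
#'   `c(arrival_ts = "ankomst")`), or the path to a JSON file holding such a
#'   mapping. Unmapped fields use their canonical names.
#' @param delim Field delimiter, default comma.
#' @return Visit-log data frame of the valid rows, with attribute
#'   `"diagnostics"`: a data.frame of `row` (1-based data row in the file) and
#'   `message` for each rejected row.
#' @export
read_visit_log <- function(path, dialect = NULL, delim = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect))
    dialect <- unlist(jsonlite::read_json(dialect, simplifyVector = TRUE))
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  src <- stats::setNames(.VISIT_COLUMNS, .VISIT_COLUMNS)
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    unknown <- setdiff(names(dialect), .VISIT_COLUMNS)
    if (length(unknown))
      stop("dialect maps unknown fields: ", paste(unknown, collapse = ", "))
    src[names(dialect)] <- dialect
  }
  miss <- src[!src %in% names(raw)]
  if (length(miss))
    stop("required column(s) not found in ", path, ": ",
         paste(sprintf("%s (for %s)", miss, names(miss)), collapse = ", "))
  v <- data.frame(
    visit_id = raw[[src["visit_id"]]],
    patient_id = raw[[src["patient_id"]]],
    ed_id = raw[[src["ed_id"]]],
    arrival_ts = parse_ts(raw[[src["arrival_ts"]]]),
    physician_ts = parse_ts(raw[[src["physician_ts"]]]),
    departure_ts = parse_ts(raw[[src["departure_ts"]]]),
    age_years = suppressWarnings(as.integer(raw[[src["age_years"]]])),
    sex = tolower(trimws(raw[[src["sex"]]])),
    ambulance = .parse_flag(raw[[src["ambulance"]]]),
    admitted = .parse_flag(raw[[src["admitted"]]]),
    acuity = suppressWarnings(as.integer(raw[[src["acuity"]]])),
    complaint = raw[[src["complaint"]]],
    stringsAsFactors = FALSE
  )
  dd <- trimws(raw[[src["death_date"]]])
  dd[!nzchar(dd)] <- NA_character_
  v$death_date <- as.Date(dd, format = "%Y-%m-%d")
  diag <- .visit_row_problems(v)
  keep <- setdiff(seq_len(nrow(v)), diag$row)
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diag
  out
}

#' Write a visit log as delimited text
#'
#' Inverse of [read_visit_log()]: timestamps at minute resolution, absent
#' values as empty strings. A written log re-reads to identical records.
#'
#' @param visits Visit-log data frame.
#' @param path Output path.
#' @param delim Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_visit_log <- function(visits, path, delim = ",") {
  out <- data.frame(
    visit_id = visits$visit_id,
    patient_id = visits$patient_id,
    ed_id = visits$ed_id,
    arrival_ts = fmt_ts(visits$arrival_ts),
    physician_ts = fmt_ts(visits$physician_ts),
    departure_ts = fmt_ts(visits$departure_ts),
    age_years = visits$age_years,
    sex = visits$sex,
    ambulance = tolower(as.character(visits$ambulance)),
    admitted = tolower(as.character(visits$admitted)),
    acuity = visits$acuity,
    complaint = visits$complaint,
    death_date = ifelse(is.na(visits$death_date), "",
                        format(visits$death_date, "%Y-%m-%d")),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Apply the study exclusion filters to a visit log
#'
#' Removes, in fixed precedence so the tallies are deterministic:
#' (a) duplicate registrations — identical `(patient_id, ed_id, arrival_ts)`,
#' keeping the first in file order; (b) implausibly long stays — length of
#' stay strictly greater than 72 h; (c) inconsistent mortality — death date
#' strictly before the calendar date of arrival. A record excluded by an
#' earlier rule is not counted again under a later one.
#'
#' @param visits Visit-log data frame.
#' @return A list with `visits` (the retained records) and `report`, a
#'   `clean_report` holding `n_input`, `n_duplicates`, `n_long_los`,
#'   `n_bad_mortality` and `n_retained` (which always sum up).
#' @export
clean_visits <- function(visits) {
  n <- nrow(visits)
  if (n == 0L) {
    rep0 <- structure(list(n_input = 0L, n_duplicates = 0L, n_long_los = 0L,
                           n_bad_mortality = 0L, n_retained = 0L),
                      class = "clean_report")
    return(list(visits = visits, report = rep0))
  }
  dup <- duplicated(data.frame(visits$patient_id, visits$ed_id,
                               as.numeric(visits$arrival_ts)))
  los_h <- as.numeric(visits$departure_ts - visits$arrival_ts,
                      units = "hours")
  long <- !dup & los_h > 72
  bad <- !dup & !long & !is.na(visits$death_date) &
    visits$death_date < as.Date(visits$arrival_ts, tz = "UTC")
  keep <- !(dup | long | bad)
  out <- visits[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- structure(list(
    n_input = n,
    n_duplicates = sum(dup),
    n_long_los = sum(long),
    n_bad_mortality = sum(bad),
    n_retained = sum(keep)
  ), class = "clean_report")
  list(visits = out, report = report)
}

#' @export
print.clean_report <- function(x, ...) {
  cat("Visit-log cleaning report\n")
  cat(sprintf("  input records:        %d\n", x$n_input))
  cat(sprintf("  duplicates removed:   %d\n", x$n_duplicates))
  cat(sprintf("  LOS > 72 h removed:   %d\n", x$n_long_los))
  cat(sprintf("  bad mortality removed:%d\n", x$n_bad_mortality))
  cat(sprintf("  retained:             %d\n", x$n_retained))
  invisible(x)
}
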