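test_that("complaint categories rank by absolute 30-day deaths with lexicographic ties", {
  mk_deaths <- function(code, n_total, n_dead) {
    arr <- rep("2017-02-01 10:00", n_total)
    death <- c(rep("2017-02-10", n_dead), rep(NA, n_total - n_dead))
    mk_visits(arr, rep("2017-02-01 12:00", n_total), complaint = code,
              death = death)
  }
  codes <- sprintf("C%02d", 1:12)
  v <- do.call(rbind, lapply(1:12, function(i)
    mk_deaths(codes[i], 15, 13 - i)))  # C01 has 12 deaths ... C12 has 1
  map <- top_complaints(v, k = 10)
  expect_equal(sort(names(map)), sort(codes))
  expect_equal(unname(map[codes[1:10]]), codes[1:10])
  expect_equal(unname(map[codes[11:12]]), c("OTHER", "OTHER"))

  few <- do.call(rbind, lapply(1:3, function(i) mk_deaths(codes[i], 5, i)))
  expect_equal(unname(top_complaints(few, 10)), codes[1:3])

  # tie at rank k: lexicographically smaller code kept
  tie <- rbind(mk_deaths("AAA", 10, 2), mk_deaths("ZZZ", 10, 2),
               mk_deaths("MMM", 10, 5))
  map2 <- top_complaints(tie, k = 2)
  expect_equal(unname(map2[c("MMM", "AAA", "ZZZ")]),
               c("MMM", "AAA", "OTHER"))
})

test_that("covariate encoding applies the band, merge-invert and event-time rules", {
  v <- mk_visits(rep("2017-02-01 10:00", 4), rep("2017-02-01 12:00", 4),
                 age = c(80, 79, 18, 40), acuity = c(5, 1, 4, 2),
                 death = c("2017-02-03", NA, NA, NA))
  v$exposure <- factor(rep("REF_LT85", 4), levels = EXPOSURE_LEVELS)
  rows <- encode_covariates(v, c(OTH = "OTHER"), horizon_days = 7)
  expect_equal(as.character(rows$age_band), c("80+", "60-79", "0-18",
                                              "40-59"))
  expect_equal(as.integer(as.character(rows$acuity_inv)), c(1, 4, 1, 3))
  expect_equal(rows$event, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(rows$time, c(2.5, 7, 7, 7))
  expect_true(all(rows$time <= 7))
})

test_that("a death on the horizon day itself is censored, not an event", {
  v <- mk_visits("2017-02-01 10:00", "2017-02-01 12:00",
                 death = "2017-02-08")
  v$exposure <- factor("REF_LT85", levels = EXPOSURE_LEVELS)
  r7 <- encode_covariates(v, c(OTH = "OTHER"), 7)
  expect_false(r7$event)
  expect_equal(r7$time, 7)
  r30 <- encode_covariates(v, c(OTH = "OTHER"), 30)
  expect_true(r30$event)
  expect_equal(r30$time, 7.5)
})

test_that("the Cox fit recovers a known two-group hazard ratio", {
  withr::local_seed(2017)
  n <- 5000
  mk_rows <- function(n, rate, level) {
    tt <- rexp(n, rate)
    data.frame(
      time = pmin(tt, 30), event = tt < 30,
      exposure = factor(level, levels = EXPOSURE_LEVELS),
      age_band = factor("40-59"), sex = factor("female"),
      ambulance = FALSE, admitted = FALSE,
      acuity_inv = factor(1, levels = 1:4),
      complaint_cat = factor("OTHER")
    )
  }
  rows <- rbind(mk_rows(n, 0.02, "REF_LT85"), mk_rows(n, 0.04, "GT95"))
  fit <- fit_cox(rows)
  hr <- fit$hr[fit$hr$level == "GT95", ]
  expect_gt(hr$hr, 1.8)
  expect_lt(hr$hr, 2.2)
  expect_true(hr$ci_low <= hr$hr && hr$hr <= hr$ci_high)
  expect_equal(fit$n_rows, 2 * n)

  # invariant to row ordering
  perm <- sample.int(nrow(rows))
  fit2 <- fit_cox(rows[perm, ])
  expect_equal(fit2$hr, fit$hr, tolerance = 1e-8)
})

test_that("degenerate designs are estimation errors", {
  v <- mk_visits(rep("2017-02-01 10:00", 10), rep("2017-02-01 12:00", 10),
                 death = c("2017-02-02", rep(NA, 9)))
  v$exposure <- factor(rep("REF_LT85", 10), levels = EXPOSURE_LEVELS)
  rows <- encode_covariates(v, c(OTH = "OTHER"), 7)
  expect_error(fit_cox(rows), "contrast")
  v$death_date <- as.Date(NA)
  v$exposure <- factor(rep(c("REF_LT85", "GT95"), 5),
                       levels = EXPOSURE_LEVELS)
  rows2 <- encode_covariates(v, c(OTH = "OTHER"), 7)
  expect_error(fit_cox(rows2), "events")
})

test_that("an independent covariate barely moves the exposure estimate", {
  withr::local_seed(77)
  n <- 8000
  tt <- rexp(n, 0.02 * ifelse(rep(c(TRUE, FALSE), each = n / 2), 2, 1))
  rows <- data.frame(
    time = pmin(tt, 30), event = tt < 30,
    exposure = factor(rep(c("GT95", "REF_LT85"), each = n / 2),
                      levels = EXPOSURE_LEVELS),
    age_band = factor("40-59"), sex = factor("female"),
    ambulance = sample(c(TRUE, FALSE), n, replace = TRUE),  # pure noise
    admitted = FALSE, acuity_inv = factor(1, levels = 1:4),
    complaint_cat = factor("OTHER")
  )
  with_cov <- fit_cox(rows)$hr$hr[1]
  rows$ambulance <- FALSE
  without_cov <- fit_cox(rows)$hr$hr[1]
  expect_lt(abs(with_cov / without_cov - 1), 0.02)
})

test_that("the outcome table reports exact percentages and HH:MM stay summaries", {
  withr::local_seed(8)
  v <- rand_visits(200)
  v$death_date[1:9] <- as.Date(v$arrival_ts[1:9], tz = "UTC") + c(0, 0, 1,
                                                                  5, 6, 10,
                                                                  20, 29, 31)
  v$exposure <- factor(sample(EXPOSURE_LEVELS[1:4], 200, replace = TRUE),
                       levels = EXPOSURE_LEVELS)
  tab <- mortality_table(v)
  expect_equal(tab$exposure, EXPOSURE_LEVELS)
  for (h in c(1, 7, 30)) {
    dcol <- tab[[sprintf("deaths_%dd", h)]]
    pcol <- tab[[sprintf("mortality_%dd_pct", h)]]
    expect_equal(pcol[tab$n > 0],
                 round(100 * dcol[tab$n > 0] / tab$n[tab$n > 0], 2))
    expect_true(all(dcol <= tab$n, na.rm = TRUE))
  }
  expect_equal(sum(tab$deaths_30d, na.rm = TRUE), 8)  # day 31 is censored
  expect_true(all(is.na(tab[tab$n == 0, "los_mean"])))
  expect_equal(tab$los_mean_hhmm, fmt_hhmm(tab$los_mean))
})

test_that("repeat-visit fractions match hand-counted toy cohorts", {
  # every patient one visit
  v1 <- mk_visits(c("2017-02-01 10:00", "2017-02-02 10:00"),
                  c("2017-02-01 12:00", "2017-02-02 12:00"),
                  patient = c("P1", "P2"))
  expect_equal(unname(repeat_visit_summary(v1, 7)), c(NA_real_, 0))

  # P1 dies after a re-visit within 7 d; P2 re-visits and survives;
  # P3, P4 single visits, P4 dies
  v2 <- mk_visits(
    arrival = c("2017-02-01 10:00", "2017-02-04 10:00",
                "2017-02-01 10:00", "2017-02-20 10:00",
                "2017-02-01 10:00", "2017-02-01 10:00"),
    departure = c("2017-02-01 12:00", "2017-02-04 12:00",
                  "2017-02-01 12:00", "2017-02-20 12:00",
                  "2017-02-01 12:00", "2017-02-01 12:00"),
    patient = c("P1", "P1", "P2", "P2", "P3", "P4"),
    death = c(NA, "2017-02-05", NA, NA, NA, "2017-02-03")
  )
  out <- repeat_visit_summary(v2, 7)
  expect_equal(unname(out["dying"]), 50)      # P1 yes, P4 no
  expect_equal(unname(out["surviving"]), 0)   # P2's visits are 19 d apart
  # invariant to patient relabeling
  v3 <- v2
  v3$patient_id <- chartr("1234", "9876", v3$patient_id)
  expect_equal(unname(repeat_visit_summary(v3, 7)), unname(out))
})
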