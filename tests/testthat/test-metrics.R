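w <- function(a, b) time_window(ts(a), ts(b))

test_that("presence overlap follows the half-open minute-resolution convention", {
  win <- w("2017-01-01 10:00", "2017-01-01 11:00")
  v <- mk_visits(
    arrival = c("2017-01-01 07:00", "2017-01-01 09:00",
                "2017-01-01 10:30", "2017-01-01 08:00"),
    departure = c("2017-01-01 08:00", "2017-01-01 12:00",
                  "2017-01-01 12:00", "2017-01-01 10:00"))
  expect_equal(present_interval(v, win), c(0, 1, 0.5, 0))
  # the visit departing exactly at window start is not present
  expect_equal(census_during(v, "A", win), 2L)
})

test_that("census counts distinct overlapping visits only", {
  win <- w("2017-01-01 10:00", "2017-01-01 11:00")
  expect_equal(census_during(mk_visits(character(), character()), "A", win),
               0L)
  v <- mk_visits(
    arrival = c("2017-01-01 09:50", "2017-01-01 10:10", "2017-01-01 10:40",
                "2017-01-01 13:00"),
    departure = c("2017-01-01 10:20", "2017-01-01 11:30", "2017-01-01 10:55",
                  "2017-01-01 14:00"))
  expect_equal(census_during(v, "A", win), 3L)
  expect_equal(census_during(v, "B", win), 0L)
})

test_that("patient-hours is presence time normalized by census, absent at census zero", {
  win <- w("2017-01-01 10:00", "2017-01-01 11:00")
  one <- mk_visits("2017-01-01 09:00", "2017-01-01 12:00")
  expect_equal(patient_hours(one, "A", win), 1.0)
  two <- mk_visits(c("2017-01-01 09:00", "2017-01-01 10:30"),
                   c("2017-01-01 12:00", "2017-01-01 12:00"))
  expect_equal(patient_hours(two, "A", win), 0.75)
  expect_true(is.na(patient_hours(one, "A",
                                  w("2017-01-01 13:00", "2017-01-01 14:00"))))
})

test_that("time-to-physician averages realized waits of patients waiting in the window", {
  win <- w("2017-01-01 01:00", "2017-01-01 02:00")
  none <- mk_visits("2017-01-01 01:00", "2017-01-01 03:00")
  expect_true(is.na(time_to_physician(none, "A", win)))
  one <- mk_visits("2017-01-01 00:30", "2017-01-01 03:00",
                   physician = "2017-01-01 02:00")
  expect_equal(time_to_physician(one, "A", win), 1.5)
  two <- mk_visits(c("2017-01-01 00:30", "2017-01-01 01:10"),
                   c("2017-01-01 05:00", "2017-01-01 05:00"),
                   physician = c("2017-01-01 02:30", "2017-01-01 02:10"))
  expect_equal(time_to_physician(two, "A", win), 1.5)
})

test_that("the mSEAL score matches its linear form, clamps into [1,6], rejects negatives", {
  expect_equal(mseal_score(0, 0, clamp = FALSE), 1.485)
  expect_equal(mseal_score(0.3, 1.0, clamp = FALSE), 4.5765)
  expect_equal(mseal_score(1.0, 10, clamp = TRUE), 6.0)
  expect_equal(mseal_score(0, 0, clamp = TRUE), 1.485)
  expect_error(mseal_score(-0.1, 1), "non-negative")
  # monotone non-decreasing in both arguments
  withr::local_seed(1)
  ph <- runif(50); ttp <- runif(50, 0, 4)
  expect_true(all(mseal_score(ph + 0.05, ttp) >= mseal_score(ph, ttp)))
  expect_true(all(mseal_score(ph, ttp + 0.5) >= mseal_score(ph, ttp)))
})

test_that("occupancy is instantaneous presence over beds", {
  t0 <- ts("2017-01-01 12:00")
  v <- mk_visits(rep("2017-01-01 11:00", 24), rep("2017-01-01 13:00", 24))
  expect_equal(occupancy_at(v, "A", t0, 16), 1.5)
  expect_equal(occupancy_at(v, "B", t0, 16), 0)
  leaving <- mk_visits("2017-01-01 11:00", "2017-01-01 12:00")
  expect_equal(occupancy_at(leaving, "A", t0, 10), 0)
  expect_error(occupancy_at(v, "A", t0, 0), "beds")
})

test_that("the hourly series equals independent per-window recomputation", {
  withr::local_seed(11)
  v <- rand_visits(60, base = "2017-03-01 00:00", span_h = 48)
  period <- w("2017-03-01 00:00", "2017-03-03 06:00")
  m <- hourly_metrics(v, c(A = 10), period = period)
  expect_equal(nrow(m), 54L)
  for (k in sample.int(nrow(m), 12)) {
    win <- time_window(m$hour_start[k] - 3600, m$hour_start[k])
    expect_equal(m$census[k], census_during(v, "A", win))
    expect_equal(m$patient_hours[k], patient_hours(v, "A", win))
    expect_equal(m$time_to_physician[k], time_to_physician(v, "A", win))
    expect_equal(m$occupancy_rate[k],
                 occupancy_at(v, "A", m$hour_start[k], 10))
    expect_equal(m$mseal[k],
                 if (is.na(m$patient_hours[k]) ||
                     is.na(m$time_to_physician[k])) NA_real_
                 else mseal_score(m$patient_hours[k],
                                  m$time_to_physician[k], clamp = FALSE))
  }
})

test_that("hours with patients but nobody waiting get census > 0 and absent mSEAL", {
  v <- mk_visits("2017-01-01 10:00", "2017-01-01 12:00",
                 physician = "2017-01-01 10:00")  # zero wait: never 'waiting'
  m <- hourly_metrics(v, c(A = 5),
                      period = w("2017-01-01 10:00", "2017-01-01 13:00"))
  busy <- m[m$census > 0, ]
  expect_gt(nrow(busy), 0)
  expect_true(all(is.na(busy$mseal)))
  expect_true(all(!is.na(busy$patient_hours)))
  idle <- m[m$census == 0, ]
  expect_true(all(is.na(idle$patient_hours)))
})

test_that("an ED without a configured bed count is a configuration error", {
  v <- mk_visits("2017-01-01 10:00", "2017-01-01 12:00", ed = "X")
  expect_error(hourly_metrics(v, c(A = 10)), "X")
})

test_that("interval arithmetic agrees with the 1-minute-grid oracle on random fixtures", {
  withr::local_seed(99)
  for (rep in 1:40) {
    v <- rand_visits(15, span_h = 6)
    h <- ts("2017-03-01 02:00") + 3600 * sample.int(8, 1)
    win <- time_window(h - 3600, h)
    expect_equal(census_during(v, "A", win), grid_census(v, "A", win))
    expect_equal(patient_hours(v, "A", win),
                 grid_patient_hours(v, "A", win), tolerance = 1e-9)
    expect_equal(occupancy_at(v, "A", h, 7), grid_occupancy(v, "A", h, 7))
    ph <- patient_hours(v, "A", win)
    if (!is.na(ph)) expect_true(ph > 0 && ph <= 1)
  }
})
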