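ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

test_that("length of stay keeps the fractional day and rejects empty stays", {
  expect_equal(compute_los(ts("2016-01-01T10:00:00"), ts("2016-01-05T12:24:00")),
               4.1)
  expect_equal(compute_los(ts("2016-01-01T00:00:00"), ts("2016-01-02T00:00:00")),
               1.0)
  expect_error(compute_los(ts("2016-01-01T10:00:00"), ts("2016-01-01T10:00:00")),
               "positive")
})

test_that("log transform is the natural logarithm", {
  expect_equal(log_transform_los(1), 0)
  expect_equal(log_transform_los(exp(1)), 1)
  expect_equal(log_transform_los(4.1), 1.410987, tolerance = 1e-6)
  expect_error(log_transform_los(0), "positive")
})

test_that("escalation triggers on ICU/IMCU stays, ventilation, daytime BiPAP and listed vasopressors", {
  rec <- list(id = "H1", admit = "2016-01-01T00:00:00",
              discharge = "2016-01-04T00:00:00")
  esc <- function(cohort, cfg = escalation_config())
    unname(escalation_of_care(cohort, cfg))

  expect_true(esc(make_cohort(list(rec), events = list(
    list(id = "H1", kind = "bipap", time = "2016-01-02T09:00:00")))))
  expect_false(esc(make_cohort(list(rec), events = list(
    list(id = "H1", kind = "bipap", time = "2016-01-02T21:00:00")))))
  # the daytime window is half-open: 08:00 counts, 20:00 does not
  expect_true(esc(make_cohort(list(rec), events = list(
    list(id = "H1", kind = "bipap", time = "2016-01-02T08:00:00")))))
  expect_false(esc(make_cohort(list(rec), events = list(
    list(id = "H1", kind = "bipap", time = "2016-01-02T20:00:00")))))

  expect_true(esc(make_cohort(list(rec), events = list(
    list(id = "H1", kind = "vasopressor", time = "2016-01-02T12:00:00",
         drug = "noradrenaline")))))
  expect_false(esc(make_cohort(list(rec), events = list(
    list(id = "H1", kind = "vasopressor", time = "2016-01-02T12:00:00",
         drug = "levosimendan")))))
  expect_true(esc(make_cohort(list(rec), events = list(
    list(id = "H1", kind = "mechanical_ventilation",
         time = "2016-01-02T03:00:00")))))

  icu <- make_cohort(list(rec), ward_stays = list(
    list(id = "H1", class = "icu", start = "2016-01-01T06:00:00",
         end = "2016-01-02T00:00:00")))
  expect_true(esc(icu))
  imcu <- make_cohort(list(rec), ward_stays = list(
    list(id = "H1", class = "imcu", start = "2016-01-01T06:00:00",
         end = "2016-01-02T00:00:00")))
  expect_true(esc(imcu))
  expect_false(esc(imcu, escalation_config(include_imcu = FALSE)))

  expect_false(esc(make_cohort(list(rec))))
})

test_that("escalation is monotone in added events", {
  rec <- list(id = "H1", admit = "2016-01-01T00:00:00",
              discharge = "2016-01-04T00:00:00")
  base_events <- list(list(id = "H1", kind = "bipap",
                           time = "2016-01-02T23:00:00"))
  more <- c(base_events, list(list(id = "H1", kind = "mechanical_ventilation",
                                   time = "2016-01-02T04:00:00")))
  expect_false(unname(escalation_of_care(make_cohort(list(rec),
                                                     events = base_events))))
  expect_true(unname(escalation_of_care(make_cohort(list(rec),
                                                    events = more))))
})

test_that("30-day readmission uses calendar dates with an inclusive boundary", {
  mk <- function(gap_days) make_cohort(list(
    list(id = "A", patient = "P1", admit = "2016-01-01T08:00:00",
         discharge = "2016-01-05T20:00:00"),
    list(id = "B", patient = "P1",
         admit = sprintf("2016-01-%02dT06:00:00", 5 + gap_days),
         discharge = "2016-03-01T06:00:00")))
  expect_true(readmissions_30d(mk(15)$hospitalizations)[["A"]])
  expect_true(readmissions_30d(mk(26)$hospitalizations)[["A"]])   # day 31 = gap 26
  h30 <- make_cohort(list(
    list(id = "A", patient = "P1", admit = "2016-01-01T08:00:00",
         discharge = "2016-01-05T20:00:00"),
    list(id = "B", patient = "P1", admit = "2016-02-04T06:00:00",
         discharge = "2016-02-08T06:00:00")))$hospitalizations
  expect_true(readmissions_30d(h30)[["A"]])      # exactly 30 days
  h31 <- make_cohort(list(
    list(id = "A", patient = "P1", admit = "2016-01-01T08:00:00",
         discharge = "2016-01-05T20:00:00"),
    list(id = "B", patient = "P1", admit = "2016-02-05T06:00:00",
         discharge = "2016-02-08T06:00:00")))$hospitalizations
  expect_false(readmissions_30d(h31)[["A"]])     # 31 days: outside the window
  expect_false(readmissions_30d(h31)[["B"]])     # last admission never readmitted

  single <- make_cohort(list(
    list(id = "A", patient = "P1", admit = "2016-01-01T08:00:00",
         discharge = "2016-01-05T20:00:00")))$hospitalizations
  expect_false(readmissions_30d(single)[["A"]])

  # different patients never link
  two <- make_cohort(list(
    list(id = "A", patient = "P1", admit = "2016-01-01T08:00:00",
         discharge = "2016-01-05T20:00:00"),
    list(id = "B", patient = "P2", admit = "2016-01-10T06:00:00",
         discharge = "2016-01-12T06:00:00")))$hospitalizations
  expect_false(any(readmissions_30d(two)))
})

test_that("readmission flags are invariant to record order", {
  sim <- generate_records(generator_config(n = 300, seed = 5))
  h <- sim$cohort$hospitalizations
  base <- readmissions_30d(h)
  shuffled <- h[sample(nrow(h)), , drop = FALSE]
  expect_equal(readmissions_30d(shuffled)[names(base)], base)
})

test_that("outcome construction allows death and escalation to co-occur", {
  cohort <- make_cohort(list(
    list(id = "H1", admit = "2016-01-01T00:00:00",
         discharge = "2016-01-03T00:00:00", died = TRUE),
    list(id = "H2", admit = "2016-02-01T00:00:00",
         discharge = "2016-02-03T00:00:00")),
    ward_stays = list(list(id = "H1", class = "icu",
                           start = "2016-01-01T12:00:00",
                           end = "2016-01-02T00:00:00")))
  out <- build_outcomes(cohort)
  expect_true(out$died[1] && out$escalation[1])
  expect_false(out$died[2] || out$escalation[2] || out$readmit_30d[2])
  expect_equal(out$los_days[2], 2.0)
  expect_equal(out$log_los, log(out$los_days))
})
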