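test_that("cadence is the argmax frequency, ties broken toward the lowest", {
  ws <- structure(
    list(window_start = c(0, 1), freqs = c(1.6, 1.8, 3.2),
         mean_coeffs = rbind(c(0.1, 0.5, 0.2),   # clear peak at 1.8
                             c(0.5, 0.2, 0.5)),  # tie 1.6 vs 3.2
         n_samples_per_window = 10),
    class = "windowed_scalogram"
  )
  cad <- estimate_cadence(ws)
  expect_equal(cad$cadence, c(1.8, 1.6))
  expect_equal(cad$peak_coeff, c(0.5, 0.5))
})

test_that("bout steps are the half-up rounded sum of walking cadences", {
  expect_equal(count_steps_bout(make_cadence(rep(2, 60)))$steps, 120L)
  expect_equal(count_steps_bout(make_cadence(rep(1.7, 10)))$steps, 17L)
  # alternating 1.65/1.55 over 9 windows sums to 14.45 -> 14
  alt <- make_cadence(rep(c(1.65, 1.55), length.out = 9))
  expect_equal(sum(alt$cadence), 14.45)
  expect_equal(count_steps_bout(alt)$steps, 14L)
  # half-up, not banker's: 14.5 -> 15
  expect_equal(count_steps_bout(make_cadence(c(rep(2, 6), 2.5)))$steps, 15L)
  # empty bout
  expect_equal(count_steps_bout(make_cadence(rep(2, 10)), 100, 120)$steps, 0L)
  # non-walking windows contribute nothing
  mixed <- make_cadence(rep(2, 10), walking = c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(count_steps_bout(mixed)$steps, 10L)
})

test_that("bout steps are additive over any whole-second partition", {
  withr::local_seed(5)
  cad <- make_cadence(runif(120, 1.2, 2.4))
  total <- sum(cad$cadence)
  cuts <- c(0, sort(sample(1:119, 4)), 120)
  parts <- purrr::map_dbl(seq_len(length(cuts) - 1), function(i) {
    sel <- cad$window_start >= cuts[i] & cad$window_start < cuts[i + 1]
    sum(cad$cadence[sel])
  })
  expect_equal(sum(parts), total, tolerance = 1e-12)
})

test_that("the walking gate rejects constant signals and accepts oscillation", {
  flat <- make_recording(rep(0, 300), rep(0, 300), rep(1, 300))
  cad <- step_cadence(flat)
  expect_false(any(cad$walking))
  expect_equal(count_steps_bout(cad)$steps, 0L)

  t <- (0:299) / 10
  osc <- make_recording(rep(0, 300), rep(0, 300),
                        1 + 0.3 * sin(2 * pi * 2 * t))
  cad2 <- step_cadence(osc)
  expect_true(mean(cad2$walking) > 0.9)
})

test_that("external walking segments bypass the gate exactly", {
  flat <- make_recording(rep(0, 300), rep(0, 300), rep(1, 300))
  cad <- step_cadence(flat, segments = data.frame(start = 3, end = 8))
  expect_identical(which(cad$walking), 4:8)  # windows starting at 3..7 s
})

test_that("minute aggregation attributes windows by start time", {
  cad <- make_cadence(rep(2, 60))
  m <- aggregate_minutes(cad)
  expect_equal(m$steps, 120)

  # a bout straddling a minute boundary splits 30 s / 30 s
  cad2 <- make_cadence(rep(2, 60), start = 30)
  m2 <- aggregate_minutes(cad2)
  expect_equal(m2$steps, c(60, 60))

  cad3 <- make_cadence(rep(2, 60), walking = FALSE)
  expect_equal(aggregate_minutes(cad3)$steps, 0)
})

test_that("duty-cycle recovery multiplies by (on+off)/on for flagged series", {
  expect_equal(sampling_scheme(10, 20)$recovery_factor, 3)
  expect_equal(sampling_scheme(30, 30)$recovery_factor, 2)

  m <- make_minutes(c(20, 0, 25), duty_cycled = TRUE)
  out <- apply_recovery(m, sampling_scheme(10, 20))
  expect_equal(out$steps, c(60, 0, 75))
  out2 <- apply_recovery(make_minutes(c(25), duty_cycled = TRUE),
                         sampling_scheme(30, 30))
  expect_equal(out2$steps, 50)
  # continuous series pass through untouched
  cont <- make_minutes(c(20, 25))
  expect_equal(apply_recovery(cont, sampling_scheme())$steps, c(20, 25))
})

test_that("joint-zero filtering keeps only minutes positive on both devices", {
  a <- make_minutes(c(10, 0, 7, 0))
  b <- make_minutes(c(12, 5, 0, 0), source = "wearable")
  out <- filter_joint_nonzero(a, b)
  expect_equal(nrow(out), 1)
  expect_equal(out$steps_a, 10)
  expect_equal(out$steps_b, 12)

  expect_warning(filter_joint_nonzero(make_minutes(c(0, 0)),
                                      make_minutes(c(0, 0))),
                 "nonzero")
  # disjoint grids align to the union and produce nothing
  c1 <- make_minutes(c(5, 5), start = 0)
  c2 <- make_minutes(c(5, 5), start = 7200)
  expect_warning(out2 <- filter_joint_nonzero(c1, c2))
  expect_equal(nrow(out2), 0)
})

test_that("daily totals split by calendar day and omit empty input", {
  m <- make_minutes(c(60, 60, 60), start = 3 * 86400)
  d <- daily_totals(m)
  expect_equal(d$steps, 180)

  # minutes spanning midnight fall on their own days
  m2 <- make_minutes(c(50, 70), start = 4 * 86400 - 60)
  d2 <- daily_totals(m2)
  expect_equal(nrow(d2), 2)
  expect_equal(d2$steps, c(50, 70))

  expect_equal(nrow(daily_totals(make_minutes(numeric(0)))), 0)
})

test_that("validation-day selection finds first day and first >= 1000 steps", {
  daily <- tibble::tibble(
    date = as.Date("2023-01-02") + 0:2,
    steps = c(300, 1500, 900), source = "smartphone"
  )
  sel <- select_validation_days(daily)
  expect_equal(sel$first_day, as.Date("2023-01-02"))
  expect_equal(sel$first_day_threshold, as.Date("2023-01-03"))

  none <- dplyr::mutate(daily, steps = c(300, 900, 950))
  sel2 <- select_validation_days(none)
  expect_true(is.na(sel2$first_day_threshold))

  single <- daily[2, ]
  sel3 <- select_validation_days(single)
  expect_equal(sel3$first_day, sel3$first_day_threshold)

  # a partial first day is excluded when the span is known
  span <- as.POSIXct(c("2023-01-02 08:00:00", "2023-01-05 00:00:00"),
                     tz = "UTC")
  sel4 <- select_validation_days(daily, span = span)
  expect_equal(sel4$first_day, as.Date("2023-01-03"))
})
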