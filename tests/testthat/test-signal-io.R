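test_that("accelerometer CSV parsing handles canonical and remapped columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,x,y,z", "0,0.1,0.2,0.9", "0.1,0.1,0.2,0.9",
               "0.2,0.0,0.0,1.0", "0.3,0.0,0.0,1.0"), f)
  rec <- read_accelerometer_csv(f, accel_dialect(unit = "g"))
  expect_s3_class(rec, "accel_recording")
  expect_equal(nrow(rec), 4)
  expect_identical(attr(rec, "unit"), "g")

  # shuffled column order plus a dialect remap gives the identical recording
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("az,t,ax,ay", "0.9,0,0.1,0.2", "0.9,0.1,0.1,0.2",
               "1.0,0.2,0.0,0.0", "1.0,0.3,0.0,0.0"), g)
  rec2 <- read_accelerometer_csv(
    g, accel_dialect(time_col = "t", x_col = "ax", y_col = "ay", z_col = "az")
  )
  expect_equal(as.data.frame(rec2), as.data.frame(rec))
})

test_that("unparseable rows are dropped and counted in the read report", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- sprintf("%.1f,0,0,1", (0:99) / 10)
  rows[50] <- "4.9,,0,1"
  writeLines(c("timestamp,x,y,z", rows), f)
  rec <- read_accelerometer_csv(f)
  expect_equal(nrow(rec), 99)
  expect_equal(attr(rec, "read_report")$dropped, 1)
})

test_that("format and data errors are specific", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,x,y", "0,0,0"), f)
  expect_error(read_accelerometer_csv(f), class = "stepwave_format_error")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,x,y,z", "0,0,0,1", "0.2,0,0,1", "0.1,0,0,1"), g)
  expect_error(read_accelerometer_csv(g), "row 3",
               class = "stepwave_data_error")
  expect_error(read_accelerometer_csv(tempfile()), class = "stepwave_io_error")
})

test_that("unit conversion divides by standard gravity and is idempotent", {
  rec <- accel_recording(data.frame(time = c(0, 0.1), x = c(9.80665, 0),
                                    y = c(0, 0), z = c(19.6133, 0)),
                         unit = "ms2", nominal_rate = 10)
  g <- convert_to_g(rec)
  expect_identical(attr(g, "unit"), "g")
  expect_equal(g$x[1], 1.0)
  expect_equal(g$z[1], 2.0)
  expect_equal(g$x[2], 0)
  expect_identical(convert_to_g(g), g)
  expect_error(accel_recording(data.frame(time = 0, x = 0, y = 0, z = 1),
                               unit = "furlongs"),
               class = "stepwave_config_error")
})

test_that("resampling is the identity on already-uniform 10 Hz input", {
  rec <- make_recording(rnorm(50), rnorm(50), 1 + rnorm(50))
  out <- resample_uniform(rec, 10)
  expect_equal(out$time, rec$time, tolerance = 1e-9)
  expect_equal(out$x, rec$x, tolerance = 1e-9)
  expect_equal(out$z, rec$z, tolerance = 1e-9)
})

test_that("resampling is exact on a linear ramp and bounded on a sinusoid", {
  t25 <- (0:249) / 25
  ramp <- accel_recording(data.frame(time = t25, x = t25, y = 0, z = 1),
                          unit = "g")
  out <- resample_uniform(ramp, 10)
  expect_equal(out$x, out$time, tolerance = 1e-10)

  # 2 Hz sinusoid at 50 Hz: linear interpolation chord error <= A(2*pi*f*dt)^2/8
  t50 <- (0:499) / 50
  A <- 0.5
  f <- 2
  sine <- accel_recording(
    data.frame(time = t50, x = A * sin(2 * pi * f * t50), y = 0, z = 1),
    unit = "g"
  )
  out <- resample_uniform(sine, 10)
  bound <- A * (2 * pi * f / 50)^2 / 8
  expect_lte(max(abs(out$x - A * sin(2 * pi * f * out$time))), bound)
  expect_error(resample_uniform(ramp[1, ]), class = "stepwave_data_error")
})

test_that("resampling never interpolates across recording gaps", {
  t <- c((0:49) / 10, 30 + (0:49) / 10)
  rec <- accel_recording(data.frame(time = t, x = 0, y = 0, z = 1),
                         unit = "g")
  out <- resample_uniform(rec, 10)
  inside_gap <- out$time > 5 & out$time < 30
  expect_equal(sum(inside_gap), 0)
  expect_equal(nrow(out), 100)
})

test_that("vector magnitude is the Euclidean norm and rotation invariant", {
  rec <- make_recording(c(0, 1), c(0, 2), c(1, 2))
  vm <- vector_magnitude(rec)
  expect_equal(vm$vm, c(1, 3))

  withr::local_seed(42)
  base <- make_recording(rnorm(100, 0, 0.2), rnorm(100, 0, 0.2),
                         1 + rnorm(100, 0, 0.2))
  for (k in 1:5) {
    rot <- rotate_recording(base, random_rotation(seed = k))
    expect_equal(vector_magnitude(rot)$vm, vector_magnitude(base)$vm,
                 tolerance = 1e-12)
  }

  nonuni <- accel_recording(data.frame(time = c(0, 0.1, 0.35), x = 0, y = 0,
                                       z = 1), unit = "g", nominal_rate = 10)
  expect_error(vector_magnitude(nonuni), class = "stepwave_contract_error")
})

test_that("minute-step CSVs parse in generic and Fitabase dialects", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("minute_start,steps",
               "2023-01-02T08:00:00,12", "2023-01-02T08:01:00,0",
               "2023-01-02T08:02:00,40"), f)
  m <- read_minute_steps_csv(f, minute_dialect(source = "wearable"))
  expect_equal(nrow(m), 3)
  expect_equal(m$steps, c(12, 0, 40))  # zero minutes kept at read time
  expect_s3_class(m$minute_start, "POSIXct")

  fb <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ActivityMinute,Steps",
               "1/2/2023 8:00:00 AM,12", "1/2/2023 8:01:00 AM,40"), fb)
  m2 <- read_minute_steps_csv(fb, fitabase_dialect())
  expect_equal(as.numeric(m2$minute_start[1]), as.numeric(m$minute_start[1]))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("minute_start,steps", "2023-01-02T08:00:00,1",
               "2023-01-02T08:00:00,2"), dup)
  expect_error(read_minute_steps_csv(dup), "08:00",
               class = "stepwave_data_error")
})

test_that("canonical CSV write/read round-trips a recording", {
  rec <- make_recording(rnorm(20), rnorm(20), 1 + rnorm(20))
  f <- withr::local_tempfile(fileext = ".csv")
  write_accelerometer_csv(rec, f)
  back <- read_accelerometer_csv(f)
  expect_equal(back$time, rec$time)
  expect_equal(back$x, rec$x)
  expect_equal(back$y, rec$y)
  expect_equal(back$z, rec$z)
})
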