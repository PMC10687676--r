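#' Read a raw accelerometer CSV
#'
#' Parses a comma-separated file with one row per accelerometer sample into an
#' [accel_recording()]. Column names and units vary by export tool, so a
#' `dialect` maps them onto the canonical `time`, `x`, `y`, `z` layout and
#' declares the acceleration unit; unit autodetection is never attempted
#' (a resting magnitude near 1 vs 9.8 is ambiguous on clipped sensors).
#'
#' Timestamps may be numeric epoch seconds, epoch milliseconds
#' (`timestamp_format = "epoch_ms"`), or ISO-8601 datetimes
#' (`timestamp_format = "iso8601"`, taken at face value in UTC plus
#' `utc_offset`). Rows with any unparseable or missing value are dropped and
#' counted in the read report attached as attribute `read_report`.
#'
#' @param path Path to the CSV file.
#' @param dialect A list as produced by [accel_dialect()].
#' @return An [accel_recording()] with attribute `read_report`
#'   (`list(n_rows, n_kept, dropped)`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("timestamp,x,y,z", "0,0,0,1", "0.1,0,0,1"), f)
#' read_accelerometer_csv(f, accel_dialect(unit = "g"))
#' @export
read_accelerometer_csv <- function(path, dialect = accel_dialect()) {
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "stepwave_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c(dialect$time_col, dialect$x_col, dialect$y_col, dialect$z_col)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("CSV ", path, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "stepwave_format_error")
  }
  n_rows <- nrow(raw)
  time <- parse_timestamps(raw[[dialect$time_col]], dialect$timestamp_format,
                           dialect$utc_offset)
  x <- suppressWarnings(as.numeric(raw[[dialect$x_col]]))
  y <- suppressWarnings(as.numeric(raw[[dialect$y_col]]))
  z <- suppressWarnings(as.numeric(raw[[dialect$z_col]]))
  keep <- !(is.na(time) | is.na(x) | is.na(y) | is.na(z))
  tbl <- tibble(time = time[keep], x = x[keep], y = y[keep], z = z[keep])
  rec <- accel_recording(tbl, unit = dialect$unit,
                         nominal_rate = dialect$nominal_rate,
                         meta = dialect$meta)
  attr(rec, "read_report") <- list(
    n_rows = n_rows, n_kept = sum(keep), dropped = n_rows - sum(keep)
  )
  rec
}

#' Accelerometer CSV dialect
#'
#' Describes how a raw accelerometer CSV maps onto the canonical columns.
#'
#' @param time_col,x_col,y_col,z_col Column names in the file.
#' @param unit Declared unit of the axis columns: `"g"` or `"ms2"`.
#' @param timestamp_format One of `"epoch_s"`, `"epoch_ms"`, `"iso8601"`.
#' @param utc_offset Hours added to parsed wall-clock timestamps.
#' @param nominal_rate Declared sampling rate (Hz) or `NA`.
#' @param meta Free-form metadata list (device, body location, range).
#' @return A dialect list for [read_accelerometer_csv()].
#' @export
accel_dialect <- function(time_col = "timestamp", x_col = "x", y_col = "y",
                          z_col = "z", unit = "g",
                          timestamp_format = c("epoch_s", "epoch_ms", "iso8601"),
                          utc_offset = 0, nominal_rate = NA_real_,
                          meta = list()) {
  list(
    time_col = time_col, x_col = x_col, y_col = y_col, z_col = z_col,
    unit = normalise_unit(unit),
    timestamp_format = match.arg(timestamp_format),
    utc_offset = utc_offset, nominal_rate = nominal_rate, meta = meta
  )
}

parse_timestamps <- function(x, format, utc_offset) {
  t <- switch(format,
    epoch_s = suppressWarnings(as.numeric(x)),
    epoch_ms = suppressWarnings(as.numeric(x)) / 1000,
    iso8601 = {
      p <- as.POSIXct(x, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
      as.numeric(p)
    }
  )
  t + utc_offset * 3600
}

#' Write a recording back to canonical CSV
#'
#' Canonical layout: header `timestamp,x,y,z`, epoch seconds, unit g.
#' `read_accelerometer_csv()` on the result round-trips all fields.
#'
#' @param rec An [accel_recording()] in unit g.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accelerometer_csv <- function(rec, path) {
  if (recording_unit(rec) != "g") rec <- convert_to_g(rec)
  out <- tibble(timestamp = rec$time, x = rec$x, y = rec$y, z = rec$z)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Convert a recording to gravitational units
#'
#' Accelerations in SI units are divided by standard gravity,
#' 1 g = 9.80665 m/s^2. Idempotent on recordings already in g.
#'
#' @param rec An [accel_recording()].
#' @return The recording with `unit = "g"`.
#' @export
convert_to_g <- function(rec) {
  unit <- recording_unit(rec)
  if (is.null(unit)) {
    abort("recording has no declared unit", class = "stepwave_config_error")
  }
  if (unit == "g") return(rec)
  out <- rec
  out$x <- rec$x / G_STANDARD
  out$y <- rec$y / G_STANDARD
  out$z <- rec$z / G_STANDARD
  attr(out, "unit") <- "g"
  out
}

#' Resample a recording onto a uniform grid
#'
#' Linearly interpolates each axis onto a uniform grid at `target_rate`
#' spanning the recording. Samples separated by more than `gap_threshold`
#' seconds are treated as distinct segments and resampled independently —
#' interpolation never bridges a recording gap, so duty-cycle off-periods
#' (about 20 s on phones sampling intermittently) stay empty.
#'
#' @param rec An [accel_recording()] with at least 2 samples.
#' @param target_rate Target rate in Hz (default 10).
#' @param gap_threshold Seconds; larger inter-sample intervals are gaps
#'   (default 2).
#' @return A uniform [accel_recording()] at `target_rate`.
#' @export
resample_uniform <- function(rec, target_rate = 10, gap_threshold = 2) {
  stopifnot(target_rate > 0)
  if (nrow(rec) < 2) {
    abort("resampling needs at least 2 samples", class = "stepwave_data_error")
  }
  segs <- segment_indices(rec$time, gap_threshold)
  dt <- 1 / target_rate
  pieces <- purrr::map(segs, function(idx) {
    t <- rec$time[idx]
    if (length(idx) < 2) {
      # an isolated sample cannot anchor interpolation; keep it as-is
      return(tibble(time = t, x = rec$x[idx], y = rec$y[idx], z = rec$z[idx]))
    }
    n_out <- floor((t[length(t)] - t[1]) / dt + 1e-9) + 1
    grid <- t[1] + (seq_len(n_out) - 1) * dt
    # rule = 2 guards the last grid point against float overhang beyond t max
    tibble(
      time = grid,
      x = approx(t, rec$x[idx], xout = grid, rule = 2)$y,
      y = approx(t, rec$y[idx], xout = grid, rule = 2)$y,
      z = approx(t, rec$z[idx], xout = grid, rule = 2)$y
    )
  })
  out <- dplyr::bind_rows(pieces)
  new_accel_recording(out, unit = recording_unit(rec),
                      nominal_rate = target_rate, meta = attr(rec, "meta"))
}

#' Orientation-invariant vector magnitude
#'
#' Collapses the three axes to the Euclidean norm
#' \eqn{\sqrt{x^2 + y^2 + z^2}}, which is invariant to sensor orientation.
#' The recording must be uniform (resample first) and in g.
#'
#' @param rec A uniform [accel_recording()] in unit g.
#' @param gap_threshold Seconds; used only to tolerate segment boundaries when
#'   checking uniformity of duty-cycled recordings.
#' @return A [magnitude_signal()]. For gapped recordings the object keeps the
#'   per-segment structure: rows are still ordered in time, with gaps.
#' @export
vector_magnitude <- function(rec, gap_threshold = 2) {
  if (recording_unit(rec) != "g") {
    abort("convert the recording to g before computing magnitudes",
          class = "stepwave_contract_error")
  }
  rate <- attr(rec, "nominal_rate")
  if (is.na(rate)) {
    abort("resample to a uniform rate before computing magnitudes",
          class = "stepwave_contract_error")
  }
  dt <- diff(rec$time)
  within_segment <- dt <= gap_threshold
  # tolerance sized for epoch-scale timestamps (double eps ~2e-7 at 1.7e9 s)
  if (any(abs(dt[within_segment] - 1 / rate) > 1e-4 / rate)) {
    abort("recording is not uniform at its nominal rate; resample first",
          class = "stepwave_contract_error")
  }
  vm <- sqrt(rec$x^2 + rec$y^2 + rec$z^2)
  structure(
    tibble(time = rec$time, vm = vm),
    rate = rate,
    class = c("magnitude_signal", class(tibble()))
  )
}

#' Read a minute-level step-count CSV
#'
#' Parses a reference-device export (for example a Fitabase minute-level
#' steps file) into a minute step series: a tibble with `minute_start`
#' (POSIXct UTC, aligned to :00 seconds), `steps` (non-negative), and
#' `source` (`"wearable"` or `"smartphone"`). Zero-step minutes are kept at
#' read time; filtering is a downstream analysis decision.
#'
#' @param path Path to the CSV.
#' @param dialect A list from [minute_dialect()].
#' @return A tibble with attribute `read_report`.
#' @export
read_minute_steps_csv <- function(path, dialect = minute_dialect()) {
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "stepwave_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c(dialect$minute_col, dialect$steps_col)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("CSV ", path, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "stepwave_format_error")
  }
  n_rows <- nrow(raw)
  minute <- parse_minute_datetimes(raw[[dialect$minute_col]], dialect$datetime_format,
                                   dialect$utc_offset)
  steps <- suppressWarnings(as.numeric(raw[[dialect$steps_col]]))
  keep <- !(is.na(minute) | is.na(steps))
  minute <- minute[keep]
  steps <- steps[keep]
  dup <- duplicated(minute)
  if (any(dup)) {
    abort(paste0("duplicate minute in ", path, ": ",
                 format(minute[dup][1], tz = "UTC", usetz = TRUE)),
          class = "stepwave_data_error")
  }
  if (any(steps < 0)) {
    abort("negative step counts in minute file", class = "stepwave_data_error")
  }
  ord <- order(minute)
  out <- tibble(minute_start = minute[ord], steps = steps[ord],
                source = dialect$source)
  attr(out, "read_report") <- list(n_rows = n_rows, n_kept = sum(keep),
                                   dropped = n_rows - sum(keep))
  out
}

#' Minute-step CSV dialect
#'
#' @param minute_col,steps_col Column names; defaults follow the generic
#'   `minute_start,steps` layout. Use
#'   `minute_dialect("ActivityMinute", "Steps", datetime_format = "fitabase")`
#'   for Fitabase exports.
#' @param datetime_format `"iso8601"` or `"fitabase"`
#'   (`%m/%d/%Y %I:%M:%S %p`).
#' @param utc_offset Hours added to parsed times.
#' @param source Label for the series: `"wearable"` or `"smartphone"`.
#' @return A dialect list for [read_minute_steps_csv()].
#' @export
minute_dialect <- function(minute_col = "minute_start", steps_col = "steps",
                           datetime_format = c("iso8601", "fitabase"),
                           utc_offset = 0,
                           source = c("wearable", "smartphone")) {
  list(minute_col = minute_col, steps_col = steps_col,
       datetime_format = match.arg(datetime_format),
       utc_offset = utc_offset, source = match.arg(source))
}

#' Fitabase minute-steps dialect shortcut
#' @inheritParams minute_dialect
#' @return A dialect list with Fitabase column names and datetime format.
#' @export
fitabase_dialect <- function(utc_offset = 0, source = "wearable") {
  minute_dialect("ActivityMinute", "Steps", datetime_format = "fitabase",
                 utc_offset = utc_offset, source = source)
}

parse_minute_datetimes <- function(x, format, utc_offset) {
  p <- switch(format,
    iso8601 = as.POSIXct(x, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                        "%Y-%m-%d %H:%M:%OS")),
    fitabase = as.POSIXct(x, tz = "UTC", format = "%m/%d/%Y %I:%M:%S %p")
  )
  p <- p + utc_offset * 3600
  aligned <- as.numeric(p) %% 60 == 0
  p[!aligned & !is.na(p)] <- NA
  p
}
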