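#' Gait signal profile
#'
#' Phenomenological description of a walking acceleration signal: during
#' gait the magnitude oscillates around a local mean (gravity) at the step
#' frequency, modulated by a second harmonic (heel strikes) and a 0.5x
#' stride subharmonic (left/right asymmetry). Location presets differ in
#' amplitude, harmonic content, and noise — plausibility choices for where
#' phones are carried, not measurements of any particular device.
#'
#' @param cadence Steps per second, within 0.5–4.5 (walking: 0.8–3.0).
#' @param amplitude Oscillation amplitude about the local mean, in g.
#' @param harmonic_2,harmonic_05 Relative amplitudes of the 2x and 0.5x
#'   cadence components.
#' @param location One of `"thigh"`, `"waist"`, `"chest"`, `"arm"`,
#'   `"unspecified"`; fills unset parameters from the preset.
#' @param orientation A 3x3 rotation applied to the synthetic triaxial
#'   signal (default identity).
#' @param noise_sd Per-axis Gaussian sensor noise SD, in g.
#' @return A list of class `gait_profile`.
#' @export
gait_profile <- function(cadence = 1.8, amplitude = NULL, harmonic_2 = NULL,
                         harmonic_05 = NULL,
                         location = c("waist", "thigh", "chest", "arm",
                                      "unspecified"),
                         orientation = diag(3), noise_sd = NULL) {
  location <- match.arg(location)
  if (cadence < 0.5 || cadence > 4.5) {
    abort("cadence outside the analyzable 0.5-4.5 steps/s band",
          class = "stepwave_config_error")
  }
  preset <- switch(location,
    waist       = list(amplitude = 0.25, harmonic_2 = 0.25, harmonic_05 = 0.10, noise_sd = 0.03),
    thigh       = list(amplitude = 0.35, harmonic_2 = 0.20, harmonic_05 = 0.30, noise_sd = 0.03),
    chest       = list(amplitude = 0.20, harmonic_2 = 0.20, harmonic_05 = 0.10, noise_sd = 0.02),
    arm         = list(amplitude = 0.30, harmonic_2 = 0.30, harmonic_05 = 0.15, noise_sd = 0.05),
    unspecified = list(amplitude = 0.25, harmonic_2 = 0.25, harmonic_05 = 0.10, noise_sd = 0.03)
  )
  out <- list(
    cadence = cadence,
    amplitude = amplitude %||% preset$amplitude,
    harmonic_2 = harmonic_2 %||% preset$harmonic_2,
    harmonic_05 = harmonic_05 %||% preset$harmonic_05,
    location = location,
    orientation = orientation,
    noise_sd = noise_sd %||% preset$noise_sd
  )
  if (out$amplitude <= 0) {
    abort("walking amplitude must be positive", class = "stepwave_config_error")
  }
  if (out$harmonic_2 < 0 || out$harmonic_05 < 0) {
    abort("harmonic weights must be non-negative",
          class = "stepwave_config_error")
  }
  structure(out, class = "gait_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build the triaxial walking signal for a time vector (seconds, relative).
walk_axes <- function(t, profile, phase) {
  a <- profile$amplitude
  osc <- a * sin(2 * pi * profile$cadence * t + phase) +
    a * profile$harmonic_2 * sin(2 * pi * 2 * profile$cadence * t + 2 * phase + 0.7) +
    a * profile$harmonic_05 * sin(2 * pi * 0.5 * profile$cadence * t + 0.5 * phase + 1.3)
  # dominant vertical (gravity-aligned) component plus a small lateral sway
  sway <- 0.2 * a * sin(2 * pi * 0.5 * profile$cadence * t + phase + 2.1)
  list(x = sway, y = rep(0, length(t)), z = 1 + osc)
}

#' Simulate a walking bout with exact ground truth
#'
#' Generates a triaxial recording: gravity baseline plus a location-dependent
#' oscillation at the cadence (with harmonics), rotated by the profile's
#' orientation, with Gaussian sensor noise added in the device frame. Ground
#' truth steps are the sum of per-second cadence, exact by construction.
#' Deterministic given `seed`.
#'
#' @param profile A [gait_profile()].
#' @param duration Seconds (>= 2).
#' @param rate Sampling rate in Hz (default 10).
#' @param start Absolute start time in seconds since epoch (default 0).
#' @param seed Integer seed.
#' @return A list with `recording` (an [accel_recording()]) and `truth`
#'   (see [ground_truth()]).
#' @export
simulate_walk_bout <- function(profile = gait_profile(), duration = 60,
                               rate = 10, start = 0, seed = 1) {
  stopifnot(duration >= 2)
  withr::local_seed(seed)
  simulate_walk_segment(profile, duration, rate, start)
}

# Internal: walking segment using the current RNG state.
simulate_walk_segment <- function(profile, duration, rate, start) {
  n <- round(duration * rate)
  t_rel <- (seq_len(n) - 1) / rate
  phase <- runif(1, 0, 2 * pi)
  ax <- walk_axes(t_rel, profile, phase)
  xyz <- profile$orientation %*% rbind(ax$x, ax$y, ax$z)
  rec <- new_accel_recording(
    tibble(
      time = start + t_rel,
      x = xyz[1, ] + rnorm(n, sd = profile$noise_sd),
      y = xyz[2, ] + rnorm(n, sd = profile$noise_sd),
      z = xyz[3, ] + rnorm(n, sd = profile$noise_sd)
    ),
    unit = "g", nominal_rate = rate,
    meta = list(simulated = TRUE, location = profile$location)
  )
  sec <- start + seq_len(floor(duration)) - 1
  truth <- ground_truth(
    second = sec,
    cadence = rep(profile$cadence, length(sec)),
    segments = tibble(start = start, end = start + duration,
                      activity = "walking")
  )
  list(recording = rec, truth = truth)
}

#' Ground truth container
#'
#' Per-second true cadence plus derived minute and day totals (exact sums,
#' consistent by construction) and labeled activity segments.
#'
#' @param second Absolute integer seconds.
#' @param cadence True steps in each second (0 when not walking).
#' @param segments Tibble of `start`, `end`, `activity` intervals.
#' @return A list of class `ground_truth` with `seconds`, `minutes`, `days`,
#'   `segments`, and `total_steps`.
#' @export
ground_truth <- function(second, cadence, segments) {
  seconds <- tibble(second = second, cadence = cadence)
  minutes <- seconds |>
    dplyr::mutate(minute_start = as.POSIXct(floor(.data$second / 60) * 60,
                                            tz = "UTC", origin = "1970-01-01")) |>
    dplyr::group_by(.data$minute_start) |>
    dplyr::summarise(steps = sum(.data$cadence), .groups = "drop") |>
    dplyr::mutate(source = "truth")
  days <- minutes |>
    dplyr::mutate(date = as.Date(.data$minute_start, tz = "UTC")) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(steps = sum(.data$steps), .groups = "drop")
  structure(
    list(seconds = seconds, minutes = minutes, days = days,
         segments = segments, total_steps = sum(cadence)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %.1f steps over %d s, %d segment(s)\n",
              x$total_steps, nrow(x$seconds), nrow(x$segments)))
  invisible(x)
}

#' Simulate non-walking activity
#'
#' Specificity foils with activity-specific spectra and zero true steps:
#' * `rest` — gravity plus tiny sensor noise and slow drift;
#' * `desk_work` — low noise with sporadic small posture-shift transients;
#' * `motorized_transport` — broadband vibration plus slow road sway;
#' * `gesturing` — short arm-oscillation bursts without sustained cadence.
#'
#' @param activity Activity label.
#' @param duration Seconds.
#' @param rate Hz.
#' @param start Absolute start time (s).
#' @param seed Integer seed.
#' @return A list with `recording` and `truth` (0 steps).
#' @export
simulate_nonwalking <- function(activity = c("rest", "desk_work",
                                             "motorized_transport",
                                             "gesturing"),
                                duration = 60, rate = 10, start = 0,
                                seed = 1) {
  activity <- match.arg(activity)
  withr::local_seed(seed)
  simulate_nonwalking_segment(activity, duration, rate, start)
}

simulate_nonwalking_segment <- function(activity, duration, rate, start) {
  n <- round(duration * rate)
  t_rel <- (seq_len(n) - 1) / rate
  base <- switch(activity,
    rest = {
      drift <- 0.01 * sin(2 * pi * 0.02 * t_rel + runif(1, 0, 2 * pi))
      list(x = rnorm(n, sd = 0.004), y = rnorm(n, sd = 0.004),
           z = 1 + drift + rnorm(n, sd = 0.004))
    },
    desk_work = {
      z <- 1 + rnorm(n, sd = 0.008)
      # sporadic posture shifts: short 0.3 s half-sine transients
      n_ev <- stats::rpois(1, duration / 12)
      for (ev in seq_len(n_ev)) {
        at <- sample.int(max(1, n - 3), 1)
        z[at:(at + 2)] <- z[at:(at + 2)] + 0.03 * sin(pi * (0:2) / 2)
      }
      list(x = rnorm(n, sd = 0.008), y = rnorm(n, sd = 0.008), z = z)
    },
    motorized_transport = {
      sway <- 0.04 * sin(2 * pi * 0.2 * t_rel + runif(1, 0, 2 * pi))
      list(x = rnorm(n, sd = 0.02), y = rnorm(n, sd = 0.02),
           z = 1 + sway + rnorm(n, sd = 0.025))
    },
    gesturing = {
      z <- 1 + rnorm(n, sd = 0.01)
      x <- rnorm(n, sd = 0.01)
      # 1-2 s oscillation bursts at varying rates, ~15% duty
      n_b <- max(1, stats::rpois(1, duration / 10))
      for (b in seq_len(n_b)) {
        len <- round(runif(1, 1, 2) * rate)
        at <- sample.int(max(1, n - len), 1)
        f <- runif(1, 0.8, 2.5)
        tt <- (0:(len - 1)) / rate
        x[at:(at + len - 1)] <- x[at:(at + len - 1)] +
          0.05 * sin(2 * pi * f * tt) * sin(pi * tt / max(tt))
      }
      list(x = x, y = rnorm(n, sd = 0.01), z = z)
    }
  )
  rec <- new_accel_recording(
    tibble(time = start + t_rel, x = base$x, y = base$y, z = base$z),
    unit = "g", nominal_rate = rate,
    meta = list(simulated = TRUE, activity = activity)
  )
  sec <- start + seq_len(floor(duration)) - 1
  truth <- ground_truth(
    second = sec, cadence = rep(0, length(sec)),
    segments = tibble(start = start, end = start + duration,
                      activity = activity)
  )
  list(recording = rec, truth = truth)
}

#' Simulate a full day from an activity schedule
#'
#' Concatenates walking and non-walking segments on an absolute clock. When
#' a [sampling_scheme()] is given, samples outside on-cycles are removed —
#' they become recording gaps, not zeros — while the ground truth always
#' refers to the full, pre-masking activity.
#'
#' @param schedule A data frame (or list of rows) with columns `activity`
#'   (`"walking"` or a non-walking label), `duration` (s), and optionally
#'   `cadence` and `location` for walking rows.
#' @param scheme A [sampling_scheme()] or `NULL` for continuous recording.
#' @param start Absolute start time (s since epoch); defaults to midnight
#'   2023-01-02 UTC so day boundaries are meaningful.
#' @param rate Hz.
#' @param seed Integer seed.
#' @return A list with `recording` (masked if a scheme was given) and
#'   `truth`.
#' @export
simulate_day <- function(schedule, scheme = NULL,
                         start = as.numeric(as.POSIXct("2023-01-02",
                                                       tz = "UTC")),
                         rate = 10, seed = 1) {
  schedule <- as_tibble(schedule)
  stopifnot(all(c("activity", "duration") %in% names(schedule)))
  withr::local_seed(seed)
  t0 <- start
  recs <- list()
  secs <- list()
  cads <- list()
  segs <- list()
  for (i in seq_len(nrow(schedule))) {
    row <- schedule[i, ]
    sim <- if (row$activity == "walking") {
      prof <- gait_profile(
        cadence = if ("cadence" %in% names(row) && !is.na(row$cadence)) row$cadence else 1.8,
        location = if ("location" %in% names(row) && !is.na(row$location)) row$location else "waist"
      )
      simulate_walk_segment(prof, row$duration, rate, t0)
    } else {
      simulate_nonwalking_segment(row$activity, row$duration, rate, t0)
    }
    recs[[i]] <- sim$recording
    secs[[i]] <- sim$truth$seconds$second
    cads[[i]] <- sim$truth$seconds$cadence
    segs[[i]] <- sim$truth$segments
    t0 <- t0 + row$duration
  }
  rec_tbl <- dplyr::bind_rows(recs)
  rec <- new_accel_recording(rec_tbl, unit = "g", nominal_rate = rate,
                             meta = list(simulated = TRUE, day = TRUE))
  truth <- ground_truth(unlist(secs), unlist(cads), dplyr::bind_rows(segs))
  if (!is.null(scheme)) {
    rec <- mask_duty_cycle(rec, scheme, anchor = start)
  }
  list(recording = rec, truth = truth)
}

#' Apply a duty-cycle mask to a recording
#'
#' Keeps only samples inside on-cycles of the scheme (phase anchored at
#' `anchor`); off-cycle samples are removed entirely, leaving gaps.
#'
#' @param rec An [accel_recording()].
#' @param scheme A [sampling_scheme()].
#' @param anchor Absolute time (s) where an on-cycle begins.
#' @return The masked recording.
#' @export
mask_duty_cycle <- function(rec, scheme = sampling_scheme(),
                            anchor = NULL) {
  if (is.null(anchor)) anchor <- floor(rec$time[1])
  period <- scheme$on_duration + scheme$off_duration
  phase <- (rec$time - anchor) %% period
  keep <- phase < scheme$on_duration - 1e-9
  out <- rec[keep, ]
  new_accel_recording(out, unit = recording_unit(rec),
                      nominal_rate = attr(rec, "nominal_rate"),
                      meta = attr(rec, "meta"))
}

#' Simulate a reference device's minute-level step counts
#'
#' Emulates a wrist tracker exporting minute-level steps: true minute counts
#' scaled by a relative bias, perturbed with Gaussian noise, clipped at 0,
#' with whole minutes dropped to 0 at a dropout probability (non-wear /
#' sync loss).
#'
#' @param truth A `ground_truth` from the simulators.
#' @param bias_pct Relative bias in percent (+5 means the device reads 5%
#'   high).
#' @param minute_noise_sd SD of additive minute noise (steps).
#' @param dropout_prob Probability a minute reads 0 regardless of truth.
#' @param seed Integer seed.
#' @return A minute step series (`minute_start`, `steps`,
#'   `source = "wearable"`) with attribute `dropout_minutes`.
#' @export
simulate_reference_device <- function(truth, bias_pct = 0,
                                      minute_noise_sd = 0, dropout_prob = 0,
                                      seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  withr::local_seed(seed)
  m <- truth$minutes
  steps <- m$steps * (1 + bias_pct / 100)
  if (minute_noise_sd > 0) steps <- steps + rnorm(nrow(m), sd = minute_noise_sd)
  steps <- pmax(steps, 0)
  dropped <- runif(nrow(m)) < dropout_prob
  steps[dropped] <- 0
  out <- tibble(minute_start = m$minute_start, steps = steps,
                source = "wearable")
  attr(out, "dropout_minutes") <- m$minute_start[dropped]
  out
}

#' Labeled walking / non-walking corpus
#'
#' A mixed corpus for gate calibration and specificity checks: `n_walk`
#' walking bouts with cadences and locations cycled over presets, and
#' `n_nonwalk` non-walking items cycled over the four foil activities.
#'
#' @param n_walk,n_nonwalk Item counts (default 20 each).
#' @param duration Seconds per item.
#' @param seed Integer seed.
#' @return A tibble with columns `item`, `label`, `activity`, `cadence`,
#'   `location`, and list-columns `recording`, `truth`.
#' @export
simulate_corpus <- function(n_walk = 20, n_nonwalk = 20, duration = 60,
                            seed = 1) {
  cadences <- rep(seq(1.2, 2.4, by = 0.2), length.out = n_walk)
  locations <- rep(c("waist", "thigh", "chest", "arm"), length.out = n_walk)
  foils <- rep(c("rest", "desk_work", "motorized_transport", "gesturing"),
               length.out = n_nonwalk)
  walk <- purrr::map(seq_len(n_walk), function(i) {
    sim <- simulate_walk_bout(
      gait_profile(cadence = cadences[i], location = locations[i]),
      duration = duration, seed = seed * 1000 + i
    )
    tibble(item = i, label = "walking", activity = "walking",
           cadence = cadences[i], location = locations[i],
           recording = list(sim$recording), truth = list(sim$truth))
  })
  nonwalk <- purrr::map(seq_len(n_nonwalk), function(i) {
    sim <- simulate_nonwalking(foils[i], duration = duration,
                               seed = seed * 2000 + i)
    tibble(item = n_walk + i, label = "non-walking", activity = foils[i],
           cadence = NA_real_, location = NA_character_,
           recording = list(sim$recording), truth = list(sim$truth))
  })
  dplyr::bind_rows(c(walk, nonwalk))
}
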