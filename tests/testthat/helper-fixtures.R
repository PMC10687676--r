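# Shared fixture builders; everything is generated in code at test time.

# A cadence series with given per-window cadences, all walking unless stated.
make_cadence <- function(cadence, start = 0, walking = TRUE,
                         peak_coeff = 0.3) {
  structure(
    tibble::tibble(
      window_start = start + seq_along(cadence) - 1,
      cadence = cadence,
      peak_coeff = peak_coeff,
      walking = rep_len(walking, length(cadence))
    ),
    class = c("cadence_series", class(tibble::tibble()))
  )
}

# Uniform triaxial recording from explicit axis vectors, 10 Hz by default.
make_recording <- function(x, y, z, rate = 10, start = 0, unit = "g") {
  n <- length(x)
  accel_recording(
    data.frame(time = start + (seq_len(n) - 1) / rate, x = x, y = y, z = z),
    unit = unit, nominal_rate = rate
  )
}

# A minute step series on a given minute grid (POSIXct seconds since epoch).
make_minutes <- function(steps, start = 0, source = "smartphone",
                         duty_cycled = FALSE) {
  out <- tibble::tibble(
    minute_start = as.POSIXct(start + 60 * (seq_along(steps) - 1),
                              tz = "UTC", origin = "1970-01-01"),
    steps = steps,
    source = source
  )
  attr(out, "duty_cycled") <- duty_cycled
  out
}

# Independent direct-formula Bland-Altman oracle, deliberately written from
# the definition (sum-based moments), separate from the package code path.
ba_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  list(bias = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

# White-noise recording emulating a still sensor with per-axis noise sd.
make_noise_recording <- function(duration = 60, sd = 0.02, rate = 10,
                                 seed = 1) {
  withr::local_seed(seed)
  n <- duration * rate
  make_recording(rnorm(n, 0, sd), rnorm(n, 0, sd), 1 + rnorm(n, 0, sd),
                 rate = rate)
}
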