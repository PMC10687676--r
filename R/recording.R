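#' Accelerometer recordings and magnitude signals
#'
#' stepwave represents a raw recording as a tibble with columns `time`
#' (seconds since epoch, strictly increasing, possibly non-uniform) and
#' `x`, `y`, `z` (per-axis acceleration), plus attributes: `unit`
#' (`"g"` or `"ms2"`), `nominal_rate` (Hz or `NA`), and `meta` (free-form
#' list: device, body location, measurement range). The class is
#' `accel_recording` on top of the tibble classes so dplyr verbs still work;
#' stepwave functions re-validate and re-attach metadata where needed.
#'
#' @param data A data frame with numeric columns `time`, `x`, `y`, `z`.
#' @param unit Acceleration unit, `"g"` or `"ms2"` (metres per second squared).
#' @param nominal_rate Declared sampling rate in Hz, or `NA` if unknown.
#' @param meta Optional named list of free-form metadata.
#'
#' @return A tibble of class `accel_recording`.
#' @examples
#' rec <- accel_recording(
#'   data.frame(time = 0:3 / 10, x = 0, y = 0, z = 1),
#'   unit = "g", nominal_rate = 10
#' )
#' vector_magnitude(rec)
#' @export
accel_recording <- function(data, unit, nominal_rate = NA_real_, meta = list()) {
  stopifnot(is.data.frame(data))
  required <- c("time", "x", "y", "z")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "accelerometer data lacks column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "stepwave_format_error")
  }
  unit <- normalise_unit(unit)
  out <- as_tibble(data)[required]
  for (nm in required) {
    if (!is.numeric(out[[nm]])) {
      abort(paste0("column '", nm, "' must be numeric"),
            class = "stepwave_format_error")
    }
  }
  dt <- diff(out$time)
  if (length(dt) > 0 && any(dt <= 0)) {
    first_bad <- which(dt <= 0)[1] + 1L
    abort(paste0("timestamps not strictly increasing at row ", first_bad),
          class = "stepwave_data_error")
  }
  new_accel_recording(out, unit = unit, nominal_rate = nominal_rate, meta = meta)
}

new_accel_recording <- function(tbl, unit, nominal_rate = NA_real_, meta = list()) {
  structure(
    tbl,
    unit = unit,
    nominal_rate = nominal_rate,
    meta = meta,
    class = c("accel_recording", class(tibble()))
  )
}

normalise_unit <- function(unit) {
  if (length(unit) != 1 || is.na(unit)) {
    abort("acceleration unit must be declared ('g' or 'ms2')",
          class = "stepwave_config_error")
  }
  u <- tolower(gsub("[^a-z0-9]", "", tolower(unit)))
  if (u %in% c("g")) return("g")
  if (u %in% c("ms2", "mss", "msec2")) return("ms2")
  abort(paste0("unknown acceleration unit: '", unit, "'"),
        class = "stepwave_config_error")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf(
    "<accel_recording> %d samples, unit = %s, nominal rate = %s Hz\n",
    nrow(x), attr(x, "unit"),
    ifelse(is.na(attr(x, "nominal_rate")), "?", format(attr(x, "nominal_rate")))
  ))
  NextMethod()
}

recording_unit <- function(rec) attr(rec, "unit")

#' Rotate a recording by a fixed rotation matrix
#'
#' Applies one rigid rotation to every (x, y, z) sample. Used to verify that
#' the pipeline is invariant to sensor orientation: the vector magnitude of a
#' rotated recording is identical to that of the original.
#'
#' @param rec An [accel_recording()].
#' @param rotation A 3x3 rotation matrix (orthonormal, det +1).
#' @return The rotated `accel_recording`.
#' @export
rotate_recording <- function(rec, rotation) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    abort("rotation matrix is not orthonormal", class = "stepwave_config_error")
  }
  xyz <- rbind(rec$x, rec$y, rec$z)
  rot <- rotation %*% xyz
  out <- rec
  out$x <- rot[1, ]
  out$y <- rot[2, ]
  out$z <- rot[3, ]
  out
}

#' Draw a uniformly random 3-D rotation matrix
#'
#' Uses the QR decomposition of a Gaussian matrix (Haar measure after sign
#' correction). Deterministic given the RNG state.
#'
#' @param seed Optional integer seed applied locally.
#' @return A 3x3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Magnitude signal constructor
#'
#' A uniformly sampled, orientation-invariant vector-magnitude series: a
#' tibble with columns `time` (seconds, uniform at `rate`) and `vm`
#' (magnitude in g, non-negative), class `magnitude_signal`.
#'
#' @param time Numeric vector of seconds, uniformly spaced at `rate`.
#' @param vm Non-negative magnitudes in g.
#' @param rate Sampling rate in Hz.
#' @return A tibble of class `magnitude_signal`.
#' @export
magnitude_signal <- function(time, vm, rate) {
  stopifnot(length(time) == length(vm), rate > 0)
  if (length(time) > 1) {
    dt <- diff(time)
    # tolerance sized for epoch-scale timestamps (double eps ~2e-7 at 1.7e9 s)
    if (max(abs(dt - 1 / rate)) > 1e-4 / rate) {
      abort("magnitude signal is not uniform at the declared rate",
            class = "stepwave_contract_error")
    }
  }
  if (any(vm < 0)) {
    abort("vector magnitudes must be non-negative",
          class = "stepwave_data_error")
  }
  structure(
    tibble(time = time, vm = vm),
    rate = rate,
    class = c("magnitude_signal", class(tibble()))
  )
}

signal_rate <- function(sig) attr(sig, "rate")

#' @export
print.magnitude_signal <- function(x, ...) {
  cat(sprintf("<magnitude_signal> %d samples at %g Hz\n",
              nrow(x), attr(x, "rate")))
  NextMethod()
}

# Split indices of a timestamp vector into contiguous segments separated by
# gaps longer than gap_threshold seconds. Returns a list of index ranges.
segment_indices <- function(time, gap_threshold) {
  if (length(time) == 0) return(list())
  breaks <- which(diff(time) > gap_threshold)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(time))
  purrr::map2(starts, ends, ~ .x:.y)
}
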