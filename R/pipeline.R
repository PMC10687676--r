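#' Run the full step-counting pipeline on a raw recording
#'
#' Standardises the recording (convert to g, linear interpolation to a
#' uniform 10 Hz grid, orientation-invariant vector magnitude), computes the
#' wavelet scalogram, averages it over nonoverlapping 1-second windows, reads
#' cadence off the ridge, and gates by walking. This is the per-second heart
#' of the method; aggregate with [count_steps_bout()], [aggregate_minutes()],
#' [apply_recovery()], and [daily_totals()].
#'
#' @param rec An [accel_recording()].
#' @param target_rate Working rate in Hz (default 10).
#' @param grid A [frequency_grid()].
#' @param gate [gate_params()] for the walking gate.
#' @param segments Optional external walking segments (`start`, `end`), which
#'   bypass the gate.
#' @param gap_threshold Seconds; longer gaps separate independent segments.
#' @return A gated `cadence_series`.
#' @examples
#' sim <- simulate_walk_bout(gait_profile(cadence = 2), duration = 30, seed = 1)
#' cad <- step_cadence(sim$recording)
#' count_steps_bout(cad)
#' @export
step_cadence <- function(rec, target_rate = 10, grid = frequency_grid(),
                         gate = gate_params(), segments = NULL,
                         gap_threshold = 2) {
  rec <- convert_to_g(rec)
  rec <- resample_uniform(rec, target_rate = target_rate,
                          gap_threshold = gap_threshold)
  sig <- vector_magnitude(rec, gap_threshold = gap_threshold)
  scal <- compute_scalogram(sig, grid = grid, gap_threshold = gap_threshold)
  wscal <- window_average(scal)
  cad <- estimate_cadence(wscal)
  detect_walking(sig, cad, params = gate, segments = segments)
}

#' Count steps at second, minute, and day level
#'
#' Convenience wrapper running [step_cadence()] and all aggregations.
#'
#' @inheritParams step_cadence
#' @param scheme A [sampling_scheme()] when the recording is duty-cycled, or
#'   `NULL` for continuous recording.
#' @param source Label for the output series.
#' @return A list with tibbles `seconds` (the cadence series), `minutes`
#'   (recovered if a scheme was given), and `days`.
#' @export
count_steps <- function(rec, scheme = NULL, source = "smartphone",
                        target_rate = 10, grid = frequency_grid(),
                        gate = gate_params(), segments = NULL,
                        gap_threshold = 2) {
  cad <- step_cadence(rec, target_rate = target_rate, grid = grid,
                      gate = gate, segments = segments,
                      gap_threshold = gap_threshold)
  minutes <- aggregate_minutes(cad, source = source,
                               duty_cycled = !is.null(scheme))
  if (!is.null(scheme)) minutes <- apply_recovery(minutes, scheme)
  list(seconds = cad, minutes = minutes, days = daily_totals(minutes))
}
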