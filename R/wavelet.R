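#' Frequency grid for cadence estimation
#'
#' The candidate cadence frequencies the scalogram is evaluated on. The
#' default band, 0.5–4.5 Hz in 0.05 Hz steps, covers slow pathological
#' walking through fast walking and first harmonics while staying below the
#' Nyquist frequency of the 10 Hz working rate.
#'
#' @param f_min,f_max Band edges in Hz; `f_min > 0`, `f_max <= rate/2`.
#' @param resolution Grid step in Hz.
#' @param rate Working sampling rate in Hz (for the Nyquist check).
#' @return Numeric vector of frequencies with attributes `f_min`, `f_max`,
#'   `resolution`.
#' @export
frequency_grid <- function(f_min = 0.5, f_max = 4.5, resolution = 0.05,
                           rate = 10) {
  stopifnot(f_min > 0, resolution > 0)
  if (f_max > rate / 2 + 1e-9) {
    abort("f_max exceeds the Nyquist frequency of the working rate",
          class = "stepwave_config_error")
  }
  if (f_max <= f_min) {
    abort("f_max must exceed f_min", class = "stepwave_config_error")
  }
  freqs <- seq(f_min, f_max, by = resolution)
  structure(freqs, f_min = f_min, f_max = f_max, resolution = resolution)
}

#' Continuous wavelet scalogram of a magnitude signal
#'
#' Projects the vector-magnitude signal onto the time-frequency plane with an
#' analytic Morlet wavelet. During walking the magnitude oscillates around a
#' local mean at the step frequency, so coefficient magnitudes are maximised
#' where the analysed frequency matches the gait cadence.
#'
#' Implementation notes:
#' * the local mean (1 s moving average) is removed before the transform, so
#'   gravity and slow drift contribute nothing;
#' * the transform is evaluated per frequency in the Fourier domain with an
#'   L1-normalised analytic Morlet kernel
#'   \eqn{\hat\psi(\omega) = 2\,e^{-(a\omega - \omega_0)^2/2}} for
#'   \eqn{\omega > 0}, scale \eqn{a = \omega_0 / 2\pi f}. With this
#'   normalisation a pure tone of amplitude A produces a ridge of height
#'   approximately A exactly at its frequency, with no scale-dependent bias —
#'   important because cadence is read off as an argmax;
#' * edges are handled by reflection padding over the wavelet support; gapped
#'   (duty-cycled) signals are transformed segment by segment, never across a
#'   gap.
#'
#' @param sig A [magnitude_signal()] (uniform rate; gaps allowed between
#'   segments).
#' @param grid A [frequency_grid()].
#' @param omega0 Morlet centre frequency (rad); 6 trades time against
#'   frequency localisation the way spectral gait analyses usually do.
#' @param detrend_window Seconds of moving average removed before the
#'   transform (default 1).
#' @param gap_threshold Seconds separating independent segments (default 2).
#' @return An object of class `scalogram`: list with `time`, `freqs`, and the
#'   non-negative coefficient matrix `coeffs` (time x frequency), plus the
#'   sampling `rate`.
#' @export
compute_scalogram <- function(sig, grid = frequency_grid(),
                              omega0 = 6, detrend_window = 1,
                              gap_threshold = 2) {
  rate <- signal_rate(sig)
  if (is.null(rate)) {
    abort("input is not a magnitude_signal", class = "stepwave_contract_error")
  }
  f_min <- min(grid)
  min_len <- ceiling(rate / f_min)   # one period of the slowest analysed tone
  segs <- segment_indices(sig$time, gap_threshold)
  coeff_pieces <- list()
  time_pieces <- list()
  for (idx in segs) {
    if (length(idx) < min_len) {
      if (length(segs) == 1) {
        abort("signal shorter than one wavelet support at f_min",
              class = "stepwave_data_error")
      }
      next  # segment too short to analyse; skip (its windows produce no rows)
    }
    coeff_pieces[[length(coeff_pieces) + 1]] <-
      cwt_segment(sig$vm[idx], rate, grid, omega0, detrend_window)
    time_pieces[[length(time_pieces) + 1]] <- sig$time[idx]
  }
  if (length(coeff_pieces) == 0) {
    abort("no segment long enough to analyse at f_min",
          class = "stepwave_data_error")
  }
  structure(
    list(
      time = unlist(time_pieces),
      freqs = as.numeric(grid),
      coeffs = do.call(rbind, coeff_pieces),
      rate = rate
    ),
    class = "scalogram"
  )
}

# Analytic Morlet CWT of one uniform segment; returns |W| (n x n_freq).
cwt_segment <- function(vm, rate, freqs, omega0, detrend_window) {
  x <- vm - rolling_mean(vm, max(1L, round(detrend_window * rate)))
  n <- length(x)
  # reflect-pad over the widest wavelet support (4 envelope SDs at f_min)
  pad <- min(n - 1L, ceiling(4 * omega0 / (2 * pi * min(freqs)) * rate))
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  np <- length(xp)
  xh <- fft(xp)
  omega <- 2 * pi * (seq_len(np) - 1) / np * rate
  pos <- omega > 0 & omega <= pi * rate   # positive-frequency half
  out <- matrix(0, nrow = n, ncol = length(freqs))
  for (j in seq_along(freqs)) {
    a <- omega0 / (2 * pi * freqs[j])
    psi <- numeric(np)
    psi[pos] <- 2 * exp(-0.5 * (a * omega[pos] - omega0)^2)
    w <- fft(xh * psi, inverse = TRUE) / np
    out[, j] <- Mod(w[pad + seq_len(n)])
  }
  out
}

# Centered moving average with shrinking windows at the edges.
rolling_mean <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  half <- k %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d samples x %d frequencies (%.2f-%.2f Hz) at %g Hz\n",
              length(x$time), length(x$freqs), min(x$freqs), max(x$freqs),
              x$rate))
  invisible(x)
}

#' @describeIn compute_scalogram Long-format view of the coefficients, one
#'   row per (time, frequency) pair — convenient for ggplot2.
#' @param x A `scalogram`.
#' @param ... Unused.
#' @export
tidy.scalogram <- function(x, ...) {
  tibble(
    time = rep(x$time, times = length(x$freqs)),
    freq = rep(x$freqs, each = length(x$time)),
    coefficient = as.vector(x$coeffs)
  )
}

#' Average a scalogram over nonoverlapping one-second windows
#'
#' Splits the scalogram into nonoverlapping 1-second windows aligned to
#' integer seconds of the absolute clock and averages the coefficient
#' magnitudes inside each window. Only complete windows (a full second of
#' samples) are kept; a trailing (or leading) partial window is dropped.
#'
#' @param scal A `scalogram` from [compute_scalogram()].
#' @return An object of class `windowed_scalogram`: list with `window_start`
#'   (integer seconds), `freqs`, `mean_coeffs` (window x frequency), and
#'   `n_samples_per_window`.
#' @export
window_average <- function(scal) {
  stopifnot(inherits(scal, "scalogram"))
  n_per <- round(scal$rate)
  win <- floor(scal$time + 1e-9)
  counts <- table(win)
  complete <- as.numeric(names(counts))[as.integer(counts) == n_per]
  if (length(complete) == 0) {
    abort("scalogram spans less than one complete second",
          class = "stepwave_data_error")
  }
  keep <- win %in% complete
  grp <- factor(win[keep], levels = sort(complete))
  mean_coeffs <- apply(scal$coeffs[keep, , drop = FALSE], 2, function(col) {
    tapply(col, grp, mean)
  })
  mean_coeffs <- matrix(mean_coeffs, nrow = length(complete),
                        dimnames = NULL)
  structure(
    list(
      window_start = sort(complete),
      freqs = scal$freqs,
      mean_coeffs = mean_coeffs,
      n_samples_per_window = n_per
    ),
    class = "windowed_scalogram"
  )
}

#' @export
print.windowed_scalogram <- function(x, ...) {
  cat(sprintf("<windowed_scalogram> %d windows x %d frequencies\n",
              length(x$window_start), length(x$freqs)))
  invisible(x)
}
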