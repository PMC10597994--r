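# slowly varying unit-SD modulation signal (moving-average smoothed noise)
slow_modulation <- function(n, fs, window_s = 20) {
  w <- max(3L, as.integer(round(window_s * fs)))
  x <- stats::filter(stats::rnorm(n + 2L * w), rep(1 / w, w), sides = 2)
  x <- x[(w + 1L):(w + n)]
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  pmin(pmax(x, -2.5), 2.5)
}

#' Synthesise cardiac and respiratory monitoring traces
#'
#' Generates a pulse-oximeter-like cardiac waveform (sharp periodic pulses
#' at a nominal rate with slow rate drift) and a bellows-like respiratory
#' waveform (smooth quasi-sinusoid with amplitude and rate variation),
#' together with volume trigger times. The true cardiac peak times and the
#' instantaneous phases used for generation are attached as attributes so
#' phase-estimation code can be validated against ground truth.
#'
#' @param duration_s trace duration; must cover the scan.
#' @param fs_hz sampling rate of both traces.
#' @param cardiac_hz,resp_hz nominal cardiac and respiratory rates.
#' @param tr_s volume spacing for the trigger channel.
#' @param n_volumes number of volumes; defaults to as many as fit.
#' @param seed integer seed.
#' @return a [physio_recording()] with attributes `peak_times_s` (true
#'   cardiac peaks) and `cardiac_phase_true`, `resp_wave_true` sampled at
#'   the trace rate.
#' @export
synth_physio <- function(duration_s, fs_hz = 100, cardiac_hz = 1.1,
                         resp_hz = 0.25, tr_s = 2.6, n_volumes = NULL,
                         seed = 1L) {
  if (is.null(n_volumes)) n_volumes <- floor((duration_s - tr_s) / tr_s)
  if (duration_s < n_volumes * tr_s)
    stop("trace duration does not cover the scan", call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- as.integer(round(duration_s * fs_hz)) + 1L
  t <- (seq_len(n) - 1) / fs_hz
  # cardiac: integrate a drifting instantaneous rate, pulse-shaped waveform
  rate_c <- cardiac_hz * (1 + 0.04 * slow_modulation(n, fs_hz, 25))
  phi_c <- 2 * pi * cumsum(rate_c) / fs_hz
  phi_c <- phi_c - phi_c[1]
  cardiac <- (0.5 + 0.5 * cos(phi_c))^6 + 0.005 * stats::rnorm(n)
  n_peaks <- floor(max(phi_c) / (2 * pi))
  peak_times <- stats::approx(phi_c, t, xout = 2 * pi * seq_len(n_peaks))$y
  peak_times <- c(0, peak_times)          # phase zero at t = 0
  # respiration: amplitude-modulated quasi-sinusoid
  rate_r <- resp_hz * (1 + 0.06 * slow_modulation(n, fs_hz, 40))
  phi_r <- 2 * pi * cumsum(rate_r) / fs_hz
  amp_r <- 1 + 0.25 * slow_modulation(n, fs_hz, 30)
  respiratory <- amp_r * sin(phi_r) + 0.02 * stats::rnorm(n)
  onsets <- (seq_len(n_volumes) - 1) * tr_s
  p <- physio_recording(cardiac, fs_hz, respiratory, fs_hz, onsets)
  attr(p, "peak_times_s") <- peak_times
  attr(p, "cardiac_phase_true") <- phi_c %% (2 * pi)
  p
}
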