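# linear-interpolated cyclic phase from an ordered peak-time vector
phase_from_peaks <- function(peaks, times) {
  if (length(peaks) < 2L)
    stop("need at least 2 cardiac peaks to define a phase", call. = FALSE)
  phi <- numeric(length(times))
  intervals <- diff(peaks)
  for (i in seq_along(times)) {
    t <- times[i]
    j <- findInterval(t, peaks)
    if (j == 0L) {                        # before first peak: extrapolate
      dt <- intervals[1]
      phi[i] <- 2 * pi * (1 - min((peaks[1] - t) / dt, 1))
    } else if (j >= length(peaks)) {      # after last peak
      dt <- intervals[length(intervals)]
      phi[i] <- 2 * pi * ((t - peaks[length(peaks)]) / dt)
    } else {
      phi[i] <- 2 * pi * (t - peaks[j]) / (peaks[j + 1] - peaks[j])
    }
  }
  phi %% (2 * pi)
}

# thresholded local-maximum peak detection with a refractory interval
find_cardiac_peaks <- function(w, rate_hz, min_interval_s = 0.25) {
  n <- length(w)
  if (n > 5L) {                       # suppress sample-level jitter
    ws <- stats::filter(w, rep(1 / 3, 3), sides = 2)
    w <- ifelse(is.na(ws), w, as.numeric(ws))
  }
  thr <- mean(w) + 0.3 * stats::sd(w)
  is_max <- c(FALSE, w[2:(n - 1)] >= w[1:(n - 2)] &
                w[2:(n - 1)] > w[3:n], FALSE)
  cand <- which(is_max & w > thr)
  if (!length(cand)) return(numeric(0))
  refr <- min_interval_s * rate_hz
  keep <- cand[1]
  for (c in cand[-1]) {
    if (c - keep[length(keep)] >= refr) keep <- c(keep, c)
    else if (w[c] > w[keep[length(keep)]]) keep[length(keep)] <- c
  }
  # sub-sample refinement by parabolic interpolation around each maximum
  off <- vapply(keep, function(i) {
    if (i <= 1L || i >= n) return(0)
    den <- w[i - 1L] - 2 * w[i] + w[i + 1L]
    if (den >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (w[i - 1L] - w[i + 1L]) / den))
  }, 0)
  (keep - 1 + off) / rate_hz
}

#' Cardiac phase at given times
#'
#' The phase advances linearly from 0 at one detected pulse peak to 2*pi at
#' the next. Peaks are found by thresholded local-maximum detection with a
#' minimum inter-peak interval.
#'
#' @param p a [physio_recording()].
#' @param times times (s) at which to evaluate the phase.
#' @param min_interval_s refractory period of the peak detector.
#' @return phases in `[0, 2*pi)`.
#' @export
cardiac_phase <- function(p, times, min_interval_s = 0.25) {
  stopifnot(inherits(p, "physio_recording"))
  peaks <- find_cardiac_peaks(p$cardiac, p$cardiac_rate_hz, min_interval_s)
  if (length(peaks) < 2L)
    stop("fewer than 2 cardiac peaks detected", call. = FALSE)
  phase_from_peaks(peaks, times)
}

#' Respiratory phase at given times
#'
#' Histogram-equalised respiratory phase: `pi * sign(dR/dt) * H(R)`, where
#' `H` is the normalised cumulative histogram (100 bins) of the respiratory
#' amplitude. Deep expiration maps to phase ~0, the extremes of
#' inspiration/expiration flow to +/- pi.
#'
#' @param p a [physio_recording()].
#' @param times times (s) at which to evaluate the phase.
#' @param n_bins histogram bins of the equalising transfer function.
#' @return phases in `(-pi, pi]`.
#' @export
respiratory_phase <- function(p, times, n_bins = 100L) {
  stopifnot(inherits(p, "physio_recording"))
  w <- p$respiratory
  if (stats::sd(w) == 0)
    stop("respiratory trace is flat", call. = FALSE)
  rate <- p$respiratory_rate_hz
  # light smoothing before differentiation to stabilise the slope sign
  k <- max(3L, as.integer(round(0.5 * rate)))
  ws <- stats::filter(w, rep(1 / k, k), sides = 2)
  ws[is.na(ws)] <- w[is.na(ws)]
  ws <- as.numeric(ws)
  n <- length(ws)
  dw <- c(ws[2] - ws[1], (ws[3:n] - ws[1:(n - 2)]) / 2, ws[n] - ws[n - 1])
  brk <- seq(min(w), max(w), length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(w, brk, rightmost.closed = TRUE),
                               1L), n_bins), nbins = n_bins)
  cumh <- cumsum(counts) / sum(counts)
  idx <- (seq_along(w) - 1) / rate
  wt <- stats::approx(idx, w, xout = times, rule = 2)$y
  st <- stats::approx(idx, dw, xout = times, rule = 2)$y
  bins <- pmin(pmax(findInterval(wt, brk, rightmost.closed = TRUE), 1L),
               n_bins)
  pi * sign(ifelse(st == 0, 1, st)) * cumh[bins]
}

#' RETROICOR Fourier regressors
#'
#' Builds `cos(m*phi_c)`, `sin(m*phi_c)`, `cos(m*phi_r)`, `sin(m*phi_r)`
#' for `m = 1..order`, evaluated at every volume onset and zero-centred.
#'
#' @param p a [physio_recording()].
#' @param volume_onsets volume acquisition onset times (s); defaults to the
#'   recording's own.
#' @param order Fourier expansion order (default 2, giving 8 columns).
#' @return an `n_volumes x (4*order)` matrix with labelled columns.
#' @export
retroicor_regressors <- function(p, volume_onsets = p$volume_onsets_s,
                                 order = 2L) {
  phi_c <- cardiac_phase(p, volume_onsets)
  phi_r <- respiratory_phase(p, volume_onsets)
  cols <- list()
  for (m in seq_len(order)) {
    cols[[paste0("retroicor_card_cos", m)]] <- cos(m * phi_c)
    cols[[paste0("retroicor_card_sin", m)]] <- sin(m * phi_c)
    cols[[paste0("retroicor_resp_cos", m)]] <- cos(m * phi_r)
    cols[[paste0("retroicor_resp_sin", m)]] <- sin(m * phi_r)
  }
  X <- do.call(cbind, cols)
  if (any(apply(X, 2, stats::sd) < 1e-12))
    stop("degenerate RETROICOR regressor (constant phase input)",
         call. = FALSE)
  sweep(X, 2, colMeans(X))
}
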