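# Zero-phase IIR filtering for matrices of time-series (columns) with
# steady-state initial conditions, and band-limited noise generation.

# direct-form II transposed filter along rows of X (n x m), vectorised over
# columns; zi is an (nfilt-1) x m matrix of initial filter states
lfilter_mat <- function(b, a, X, zi = NULL) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  b <- b / a[1]; a <- a / a[1]
  n <- nrow(X); m <- ncol(X); ns <- nfilt - 1L
  if (is.null(zi)) zi <- matrix(0, ns, m)
  Y <- matrix(0, n, m)
  z <- zi
  for (t in seq_len(n)) {
    xt <- X[t, ]
    yt <- b[1] * xt + z[1, ]
    if (ns > 1L)
      for (k in seq_len(ns - 1L))
        z[k, ] <- b[k + 1] * xt + z[k + 1, ] - a[k + 1] * yt
    z[ns, ] <- b[nfilt] * xt - a[nfilt] * yt
    Y[t, ] <- yt
  }
  Y
}

# steady-state initial state for a unit step (scaled by the first sample),
# after Gustafsson/scipy lfilter_zi
lfilter_zi <- function(b, a) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  b <- b / a[1]; a <- a / a[1]
  n <- nfilt - 1L
  A <- matrix(0, n, n)
  A[, 1] <- -a[2:nfilt]
  if (n > 1L) A[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- 1
  B <- b[2:nfilt] - a[2:nfilt] * b[1]
  solve(diag(n) - A, B)
}

# forward-backward filtering with odd-reflection padding; X is n x m
filtfilt_mat <- function(b, a, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  nfilt <- max(length(a), length(b))
  padlen <- min(n - 1L, 3L * nfilt * 2L)
  if (padlen < 1L) stop("series too short to filter", call. = FALSE)
  top <- 2 * matrix(X[1, ], padlen, ncol(X), byrow = TRUE) -
    X[(padlen + 1L):2L, , drop = FALSE]
  bot <- 2 * matrix(X[n, ], padlen, ncol(X), byrow = TRUE) -
    X[(n - 1L):(n - padlen), , drop = FALSE]
  ext <- rbind(top, X, bot)
  zi <- lfilter_zi(b, a)
  Y <- lfilter_mat(b, a, ext, zi = zi %o% ext[1, ])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y <- lfilter_mat(b, a, Y, zi = zi %o% Y[1, ])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(padlen + 1L):(padlen + n), , drop = FALSE]
}

butter_band <- function(lo_hz, hi_hz, fs_hz, order = 2L) {
  nyq <- fs_hz / 2
  if (hi_hz >= nyq)
    stop("upper cut-off ", hi_hz, " Hz is at or above Nyquist ",
         signif(nyq, 4), " Hz", call. = FALSE)
  if (lo_hz <= 0 || lo_hz >= hi_hz)
    stop("need 0 < lo < hi < Nyquist", call. = FALSE)
  bf <- signal::butter(order, c(lo_hz, hi_hz) / nyq, type = "pass")
  list(b = bf$b, a = bf$a)
}

# |H(e^{i w})|^2 of the two-pass (filtfilt) filter on a frequency grid
filtfilt_gain2 <- function(b, a, w) {
  z <- exp(1i * w)
  H <- outer(z, 0:(length(b) - 1), function(zz, k) zz^(-k)) %*% b /
    (outer(z, 0:(length(a) - 1), function(zz, k) zz^(-k)) %*% a)
  Mod(H)^2  # one gain application per pass -> |H|^2 amplitude, |H|^4 power
}

# fraction of white-noise variance surviving the two-pass band-pass
bandpass_noise_retention <- function(lo_hz, hi_hz, fs_hz, order = 2L) {
  ba <- butter_band(lo_hz, hi_hz, fs_hz, order)
  w <- seq(0, pi, length.out = 2048L)
  mean(filtfilt_gain2(ba$b, ba$a, w)^2)
}

# fraction of unit-variance noise band-limited to [lo,hi] surviving filtfilt
bandpass_band_retention <- function(lo_hz, hi_hz, fs_hz,
                                    band_lo_hz, band_hi_hz, order = 2L) {
  ba <- butter_band(lo_hz, hi_hz, fs_hz, order)
  nyq_w <- pi
  wlo <- band_lo_hz / (fs_hz / 2) * nyq_w
  whi <- band_hi_hz / (fs_hz / 2) * nyq_w
  w <- seq(wlo, whi, length.out = 1024L)
  mean(filtfilt_gain2(ba$b, ba$a, w)^2)
}

# zero-mean, unit-variance noise with support restricted to [lo, hi] Hz,
# returned as an n x k matrix of independent columns
bandlimited_noise <- function(n, k, lo_hz, hi_hz, fs_hz) {
  W <- matrix(stats::rnorm(n * k), n, k)
  F <- stats::mvfft(W)
  freq <- (seq_len(n) - 1) / n * fs_hz
  freq <- pmin(freq, fs_hz - freq)  # two-sided
  keep <- freq >= lo_hz & freq <= hi_hz
  F[!keep, ] <- 0
  X <- Re(stats::mvfft(F, inverse = TRUE)) / n
  X <- sweep(X, 2, colMeans(X))
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(X, 2, sdv, "/")
}
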