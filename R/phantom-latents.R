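#' Sample correlated band-limited network latent signals
#'
#' Draws four zero-mean, unit-variance signals whose sample correlation
#' matrix equals `latent_corr`: independent band-limited Gaussian noise is
#' orthonormalised and mixed by a Cholesky square-root factor of
#' `latent_corr`, so the imposed cross-correlation is exact at any length
#' while each signal keeps its frequency support in `band`.
#'
#' @param latent_corr positive-definite correlation matrix (k x k).
#' @param n_volumes number of samples per signal.
#' @param band frequency support `(lo, hi)` in Hz.
#' @param tr_s sampling interval in seconds.
#' @param seed integer seed; identical seeds give identical signals.
#' @param orth_to optional matrix whose column space the signals are made
#'   exactly orthogonal to (used to build mutually independent latent sets
#'   with identical imposed correlation).
#' @return an `n_volumes x k` matrix, one latent per column (named after
#'   `latent_corr`'s columns when available).
#' @export
sample_latents <- function(latent_corr, n_volumes, band = c(0.02, 0.08),
                           tr_s = 2.6, seed = 1L, orth_to = NULL) {
  check_corr_pd(latent_corr)
  k <- ncol(latent_corr)
  if (n_volumes < k + 2L) stop("n_volumes too small", call. = FALSE)
  fs <- 1 / tr_s
  if (band[2] > fs / 2) stop("latent band exceeds Nyquist", call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  W <- bandlimited_noise(n_volumes, k, band[1], band[2], fs)
  if (!is.null(orth_to)) {
    B <- qr.Q(qr(sweep(orth_to, 2, colMeans(orth_to))))
    W <- W - B %*% crossprod(B, W)
  }
  Q <- qr.Q(qr(W))                       # orthonormal, still band-limited
  Q <- sweep(Q, 2, colMeans(Q))          # guard: exact zero mean
  Z <- sweep(Q, 2, apply(Q, 2, stats::sd), "/")
  L <- t(chol(latent_corr))
  Y <- Z %*% t(L)
  colnames(Y) <- colnames(latent_corr)
  Y
}

# per-slice horn latents: sqrt(w) * global + sqrt(1-w) * slice-specific,
# with the slice-specific sets drawn orthogonal to the global set so that
# the in-slice correlation structure equals latent_corr exactly for any
# rostro-caudal coherence w
slice_latents <- function(latent_corr, n_volumes, nz, band, tr_s, seed,
                          coherence) {
  G <- sample_latents(latent_corr, n_volumes, band, tr_s, seed)
  out <- array(NA_real_, c(n_volumes, ncol(G), nz),
               dimnames = list(NULL, colnames(G), NULL))
  if (coherence >= 1) {
    for (z in seq_len(nz)) out[, , z] <- G
    return(list(global = G, by_slice = out))
  }
  for (z in seq_len(nz)) {
    M <- sample_latents(latent_corr, n_volumes, band, tr_s,
                        seed = seed + 1000L * z, orth_to = G)
    out[, , z] <- sqrt(coherence) * G + sqrt(1 - coherence) * M
  }
  list(global = G, by_slice = out)
}
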