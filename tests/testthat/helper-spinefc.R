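# shared fixtures and independent oracles used across test files

# two-pass covariance Pearson oracle, independent of stats::cor
pearson_brute <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Amari separation index of a mixing-recovery product matrix (0 = perfect
# separation up to permutation/scale)
amari_distance <- function(P) {
  P <- abs(P)
  k <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(sweep(P, 2, apply(P, 2, max), "/")) - 1)
  (r + c) / (2 * k * (k - 1))
}

# amplitude of a sinusoidal component at frequency f (Hz) by projection
fft_amp <- function(x, f, fs) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  2 * Mod(mean((x - mean(x)) * exp(-2i * pi * f * t)))
}

# independent local-maximum peak counter (no refractory logic)
count_peaks_simple <- function(w, min_sep) {
  n <- length(w)
  thr <- mean(w) + 0.5 * stats::sd(w)
  idx <- which(c(FALSE, w[2:(n - 1)] > w[1:(n - 2)] &
                   w[2:(n - 1)] > w[3:n], FALSE) & w > thr)
  if (!length(idx)) return(0L)
  keep <- idx[c(TRUE, diff(idx) >= min_sep)]
  length(keep)
}

# compact phantom used where calibrated values do not matter
fast_spec <- function(...) {
  phantom_spec(nz = 7L, n_volumes = 120L,
               gm_taper_caudal = c(0.7, 0.85),
               enlargement_z = 4L, ...)
}

# render cache so expensive subjects are built once per test run
.spinefc_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .spinefc_cache))
    assign(key, force(expr), envir = .spinefc_cache)
  get(key, envir = .spinefc_cache)
}

# default-phantom denoising inputs shared by several preprocess tests
default_denoise <- function() cached("denoise_default", {
  s <- cached("subj_default", render_subject(phantom_spec(), seed = 42))
  m <- estimate_motion_slicewise(s$series)
  moco <- apply_motion_correction(s$series, m)
  des <- build_nuisance_design(moco, s$physio, s$truth$masks, m,
                               study_config())
  list(s = s, m = m, moco = moco, des = des)
})
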