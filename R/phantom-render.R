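# Expected fraction of white-noise variance surviving the two-pass
# band-pass, and of the latent band's variance; used to scale the horn
# latents so that the denoised ROI-mean network variance fraction hits
# lambda.
horn_latent_scales <- function(spec, horn_counts) {
  fs <- 1 / spec$tr_s
  lam <- spec$network_var_fraction
  if (spec$sigma_thermal == 0) {
    # noiseless limit: any positive coupling satisfies lambda; use a
    # nominal 2% signal change
    return(matrix(0.02, nrow(horn_counts), 4,
                  dimnames = dimnames(horn_counts)))
  }
  ret_white <- bandpass_noise_retention(spec$pipeline_band_hz[1],
                                        spec$pipeline_band_hz[2], fs)
  ret_lat <- bandpass_band_retention(spec$pipeline_band_hz[1],
                                     spec$pipeline_band_hz[2], fs,
                                     spec$latent_band_hz[1],
                                     spec$latent_band_hz[2])
  n <- pmax(horn_counts, 1L)
  sigma_roi <- spec$sigma_thermal * sqrt(ret_white / n) * spec$roi_noise_calib
  sqrt(lam / (1 - lam)) * sigma_roi / (spec$baseline_gm * sqrt(ret_lat))
}

# band-limited (<= 0.025 Hz) zero-mean translation trace: slow, smooth
# postural drift rather than volume-to-volume jitter
smooth_walk <- function(n, sd, fs) {
  if (sd == 0) return(rep(0, n))
  x <- bandlimited_noise(n, 1L, min(0.001, 0.4 / (n / fs)), 0.025, fs)[, 1]
  pmin(pmax(sd * x, -2.5 * sd), 2.5 * sd)
}

#' Render one synthetic subject
#'
#' Produces the full forward model: voxel signal = tissue baseline times
#' (1 + network term + cardiac term + respiratory term + CSF pulsation +
#' slow drift) + thermal noise, followed by slicewise in-plane translation
#' of every volume. The cardiac and respiratory terms are phase-locked to
#' the synthetic physiological traces through the same Fourier basis the
#' RETROICOR regressors use; CSF pulsation is two shared temporal patterns
#' per slice that leak at low amplitude into the cord; the respiratory term
#' additionally has a slice-wide additive component in the not-spine
#' region.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return a list of class `phantom_subject` with elements `series`
#'   (a [volume_series()]), `physio` (a [physio_recording()]) and `truth`
#'   (ground-truth masks, horn labels, latents, motion, cardiac peaks and
#'   noise parameters).
#' @export
render_subject <- function(spec, seed = spec$seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  subseeds <- sample.int(1e9L, 4L)
  geom <- make_geometry(spec)
  masks <- geom$masks
  nt <- spec$n_volumes; nz <- spec$nz; nx <- spec$nx; ny <- spec$ny
  fs <- 1 / spec$tr_s
  onsets <- (seq_len(nt) - 1) * spec$tr_s

  lat <- slice_latents(spec$latent_corr, nt, nz, spec$latent_band_hz,
                       spec$tr_s, seed = subseeds[1],
                       coherence = spec$latent_slice_coherence)
  latents <- lat$global
  physio <- synth_physio(duration_s = nt * spec$tr_s + 2 * spec$tr_s,
                         tr_s = spec$tr_s, n_volumes = nt,
                         seed = subseeds[2])
  peaks <- attr(physio, "peak_times_s")
  phi_c <- phase_from_peaks(peaks, onsets)
  phi_r <- respiratory_phase(physio, onsets)
  resp_raw <- stats::approx((seq_along(physio$respiratory) - 1) /
                              physio$respiratory_rate_hz,
                            physio$respiratory, xout = onsets, rule = 2)$y
  resp_raw <- as.numeric(scale(resp_raw))

  kappa <- horn_latent_scales(spec, geom$horn_counts)
  sprof <- cord_scale_profile(spec)
  set.seed(subseeds[3])
  data <- array(0, c(nx, ny, nz, nt))
  unit_pattern <- function(x) {
    x <- x - mean(x); s <- stats::sd(x); if (s > 0) x / s else x
  }
  fourier_pattern <- function(phi) {
    basis <- cbind(cos(phi), sin(phi), cos(2 * phi), sin(2 * phi))
    unit_pattern(basis %*% stats::rnorm(4L))
  }
  structured_sd <- matrix(0, nz, 3,
                          dimnames = list(NULL, c("gm", "csf", "notspine")))
  for (z in seq_len(nz)) {
    cord <- masks$cord[, , z]; gm <- masks$gm[, , z]
    csf <- masks$csf[, , z]; nsp <- masks$notspine[, , z]
    wm <- cord & !gm
    B <- matrix(spec$baseline_bg, nx, ny)
    B[nsp] <- spec$baseline_notspine * stats::runif(sum(nsp), 0.6, 1.3)
    B[wm] <- spec$baseline_wm
    B[gm] <- spec$baseline_gm
    B[csf] <- spec$baseline_csf
    edge <- cord_edge_profile(spec, sprof[z] * spec$geom_scale)

    card_p <- fourier_pattern(phi_c)
    resp_p <- fourier_pattern(phi_r)
    u <- bandlimited_noise(nt, 2L, 0.005, 0.15, fs)
    xg <- seq(-1, 1, length.out = nt)
    drift_p <- unit_pattern(stats::rnorm(1) * xg +
                              stats::rnorm(1) * (1.5 * xg^2 - 0.5))

    ac <- spec$amp_cardiac * (cord * (0.55 + 0.9 * edge) + csf * 1.4 +
                                nsp * 0.25)
    ar <- spec$amp_resp * (cord * 0.9 + csf * 0.7 + nsp * 1.1)
    w1 <- w2 <- matrix(0, nx, ny)
    w1[csf] <- spec$amp_csf_puls * stats::runif(sum(csf), 0.7, 1.3)
    w2[csf] <- spec$amp_csf_puls * stats::runif(sum(csf), 0.7, 1.3)
    leak <- spec$amp_csf_puls * 0.10 * (0.5 + 0.5 * edge)
    w1[cord] <- leak[cord]
    w2[cord] <- 0.5 * leak[cord]
    ad <- spec$amp_drift * matrix(stats::runif(nx * ny, 0.7, 1.3), nx, ny)

    # in-plane point-spread: smooth every structural map, not the noise
    psf <- spec$psf_sigma_vox
    B <- blur_image(B, psf)
    ac <- blur_image(ac, psf); ar <- blur_image(ar, psf)
    w1 <- blur_image(w1, psf); w2 <- blur_image(w2, psf)
    ad <- blur_image(ad, psf)
    rel <- as.vector(ac) %o% as.numeric(card_p) +
      as.vector(ar) %o% as.numeric(resp_p) +
      as.vector(w1) %o% u[, 1] + as.vector(w2) %o% u[, 2] +
      as.vector(ad) %o% as.numeric(drift_p)
    for (h in HORNS) {
      kmap <- matrix(0, nx, ny)
      kmap[geom$quadrants[, , z] == QUAD_CODES[[h]]] <- kappa[z, h]
      kmap <- blur_image(kmap, psf)
      nzv <- which(as.vector(kmap) != 0)
      if (length(nzv))
        rel[nzv, ] <- rel[nzv, ] + as.vector(kmap)[nzv] %o%
          lat$by_slice[, h, z]
    }
    S <- as.vector(B) * (1 + rel)
    # slice-wide additive respiratory component in not-spine tissue
    nsp_amp <- blur_image(nsp * 0.5 * spec$amp_resp * B, psf)
    S <- S + as.vector(nsp_amp) %o% resp_raw
    if (spec$sigma_thermal > 0)
      S <- S + stats::rnorm(length(S), sd = spec$sigma_thermal)
    abs_struct <- as.vector(B) * rel
    row_sd <- sqrt(pmax(rowMeans(abs_struct^2) - rowMeans(abs_struct)^2, 0))
    structured_sd[z, ] <- c(mean(row_sd[as.vector(gm)]),
                            mean(row_sd[as.vector(csf)]),
                            mean(row_sd[as.vector(nsp)]))
    data[, , z, ] <- array(S, c(nx, ny, nt))
  }

  set.seed(subseeds[4])
  true_motion <- array(0, c(nz, nt, 2L))
  if (spec$motion_sd_vox > 0) {
    base_x <- smooth_walk(nt, spec$motion_sd_vox, fs)
    base_y <- smooth_walk(nt, spec$motion_sd_vox, fs)
    jit <- spec$motion_slice_jitter * spec$motion_sd_vox
    for (z in seq_len(nz)) {
      true_motion[z, , 1] <- base_x + smooth_walk(nt, jit, fs)
      true_motion[z, , 2] <- base_y + smooth_walk(nt, jit, fs)
    }
    for (z in seq_len(nz))
      for (t in seq_len(nt))
        data[, , z, t] <- shift_image(data[, , z, t],
                                      true_motion[z, t, 1],
                                      true_motion[z, t, 2])
  }

  series <- volume_series(data, spec$voxel_mm, spec$tr_s,
                          space_tag = "native")
  truth <- list(masks = masks, quadrants = geom$quadrants,
                horn_counts = geom$horn_counts,
                cord_area_vox = geom$cord_area_vox,
                latents = latents, latents_by_slice = lat$by_slice,
                latent_corr = spec$latent_corr,
                true_motion = true_motion, peak_times_s = peaks,
                kappa = kappa, thermal_sd = spec$sigma_thermal,
                structured_sd = structured_sd)
  structure(list(series = series, physio = physio, truth = truth,
                 spec = spec, seed = as.integer(seed)),
            class = "phantom_subject")
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat("<phantom_subject> seed", x$seed, "\n")
  print(x$series)
  invisible(x)
}
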