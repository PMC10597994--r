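test_that("phantom geometry satisfies mask invariants, symmetry and taper", {
  geom <- make_geometry(phantom_spec())
  m <- geom$masks
  expect_s3_class(m, "mask_set")           # containment checked on build
  hc <- geom$horn_counts
  expect_true(all(hc[, "LV"] == hc[, "RV"]))   # mirror-symmetric template
  expect_true(all(hc[, "LD"] == hc[, "RD"]))
  gm_per_slice <- apply(m$gm, 3, sum)
  expect_lt(gm_per_slice[1], gm_per_slice[8])  # caudal GM taper
  expect_true(all(gm_per_slice >= 1))
  # cord area peaks at the enlargement slice
  expect_identical(which.max(geom$cord_area_vox), 6L)
  # oversized horns must be rejected at the cord boundary
  big <- phantom_spec(horn_semi_mm = list(LV = c(3.5, 3), RV = c(3.5, 3),
                                          LD = c(3.5, 3), RD = c(3.5, 3)))
  expect_error(make_geometry(big), "overlaps the cord boundary")
})

test_that("latent sampler imposes the requested correlation structure", {
  n <- 20000
  id <- diag(4); dimnames(id) <- dimnames(default_latent_corr())
  L0 <- sample_latents(id, n, seed = 1)
  C0 <- cor(L0)
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.03)
  tgt <- default_latent_corr()
  L1 <- sample_latents(tgt, n, seed = 2)
  expect_lt(abs(cor(L1[, "LV"], L1[, "RV"]) - 0.478), 0.02)
  expect_lt(max(abs(colMeans(L1))), 1e-10)
  expect_equal(unname(apply(L1, 2, sd)), rep(1, 4), tolerance = 1e-8)
  # deterministic under seed
  expect_identical(L1, sample_latents(tgt, n, seed = 2))
  # band limitation: periodogram power outside [0.02, 0.08] Hz is nil
  pw <- Mod(fft(L1[, 1]))^2
  freq <- (seq_len(n) - 1) / n * (1 / 2.6)
  freq <- pmin(freq, 1 / 2.6 - freq)
  in_band <- freq >= 0.019 & freq <= 0.081
  expect_gt(sum(pw[in_band]) / sum(pw[-1]), 0.999)
  # non-positive-definite input names the offending eigenvalue
  bad <- matrix(0.99, 4, 4); bad[1, 2] <- bad[2, 1] <- -0.99; diag(bad) <- 1
  expect_error(sample_latents(bad, 100), "smallest eigenvalue")
})

test_that("synthetic physio traces have the nominal rates", {
  p <- synth_physio(525, fs_hz = 100, seed = 3)
  # ~577 cardiac peaks expected at 1.1 Hz over 525 s (slow rate drift)
  n_peaks <- count_peaks_simple(p$cardiac, min_sep = 0.4 * 100)
  expect_gt(n_peaks, 577 - 25)
  expect_lt(n_peaks, 577 + 25)
  # respiratory spectral peak inside [0.2, 0.3] Hz
  n <- length(p$respiratory)
  spec <- Mod(fft(p$respiratory - mean(p$respiratory)))[1:(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1) / n * 100
  expect_gt(freq[which.max(spec)], 0.2)
  expect_lt(freq[which.max(spec)], 0.3)
  expect_identical(p$cardiac, synth_physio(525, fs_hz = 100, seed = 3)$cardiac)
})

test_that("noiseless rendering reproduces the horn latents exactly", {
  spec <- fast_spec(sigma_thermal = 0, amp_cardiac = 0, amp_resp = 0,
                    amp_csf_puls = 0, amp_drift = 0, motion_sd_vox = 0)
  s <- render_subject(spec, seed = 5)
  for (z in c(1L, 4L)) for (h in 1:4) {
    idx <- which(s$truth$quadrants[, , z] == h, arr.ind = TRUE)
    ts <- s$series$data[idx[1, 1], idx[1, 2], z, ]
    expect_gt(cor(ts, s$truth$latents_by_slice[, h, z]), 0.999)
  }
})

test_that("default rendering hits the calibrated raw GM signal-to-noise", {
  s <- cached("subj_default", render_subject(phantom_spec(), seed = 42))
  gm <- s$truth$masks$gm
  X <- matrix(s$series$data, length(gm), dim(s$series$data)[4])[gm, ]
  ratio <- mean(rowMeans(X) / apply(X, 1, sd))
  expect_gt(ratio, 4.3 * 0.75)
  expect_lt(ratio, 4.3 * 1.25)
})

test_that("cohorts are reproducible, jittered and splittable", {
  co <- make_cohort(26, seed = 9, split = TRUE)
  expect_identical(nrow(co$manifest), 26L)
  expect_identical(sum(co$manifest$split_group == 1L), 13L)
  expect_identical(sum(co$manifest$split_group == 2L), 13L)
  # subject latent correlations are valid and jittered around the base
  for (i in c(1, 13, 26)) {
    lc <- co$specs[[i]]$latent_corr
    expect_gt(min(eigen(lc, only.values = TRUE)$values), 0)
  }
  expect_gt(sd(co$manifest$r_lv_rv), 0.03)
  expect_lt(abs(mean(co$manifest$r_lv_rv) - 0.478), 0.08)
  # identical seeds give bit-identical cohorts
  co2 <- make_cohort(26, seed = 9, split = TRUE)
  expect_identical(co$manifest, co2$manifest)
  # zero jitter: all subjects share the base correlations
  co0 <- make_cohort(4, base = phantom_spec(subject_jitter_sd = 0), seed = 2)
  expect_identical(co0$specs[[1]]$latent_corr, co0$specs[[4]]$latent_corr)
  # geometry perturbations stay small
  expect_true(all(abs(co$manifest$geom_shift_x) <= 1))
  expect_true(all(abs(co$manifest$geom_scale - 1) <= 0.05 + 1e-12))
})

test_that("denoised ROI correlations recover lambda-attenuated latents", {
  # long-run oracle identity r ~ lambda * latent_corr on a compact grid
  spec <- phantom_spec(nx = 40L, ny = 40L, nz = 3L, n_volumes = 10000L,
                       gm_taper_caudal = c(1, 1, 1), enlargement_z = 2L,
                       subject_jitter_sd = 0)
  s <- render_subject(spec, seed = 77)
  res <- analyze_subject(s, study_config(central_slices = 3L))
  lam <- spec$network_var_fraction
  tgt <- spec$latent_corr
  got <- res$networks$summary
  expect_lt(abs(got["VV"] - lam * tgt["LV", "RV"]), 0.03)
  expect_lt(abs(got["DD"] - lam * tgt["LD", "RD"]), 0.03)
  expect_lt(abs(got["VD_ipsi_L"] - lam * tgt["LV", "LD"]), 0.03)
  expect_lt(abs(got["VD_contra_LVRD"] - lam * tgt["LV", "RD"]), 0.03)
})
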