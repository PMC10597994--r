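test_that("slicewise motion estimation recovers planted translations", {
  # +/- 0.8 voxel smooth random walk, shared across slices
  spec <- fast_spec(motion_sd_vox = 0.4, motion_slice_jitter = 0)
  s <- cached("subj_motion", render_subject(spec, seed = 21))
  m <- estimate_motion_slicewise(s$series)
  err <- m - s$truth$true_motion
  expect_lt(sqrt(mean(err^2)), 0.1)
  # motion-free input gives near-zero estimates (thermal noise only)
  s0 <- cached("subj_nomotion",
               render_subject(fast_spec(motion_sd_vox = 0, amp_cardiac = 0,
                                        amp_resp = 0, amp_csf_puls = 0,
                                        amp_drift = 0), seed = 22))
  m0 <- estimate_motion_slicewise(s0$series)
  expect_lt(max(abs(m0)), 0.05)
})

test_that("rostro-caudal regularisation helps on z-smooth motion", {
  spec <- fast_spec(motion_sd_vox = 0.4, motion_slice_jitter = 0)
  s <- render_subject(spec, seed = 24)
  m1 <- estimate_motion_slicewise(s$series, reg_width = 1L)
  m3 <- estimate_motion_slicewise(s$series, reg_width = 3L)
  rms <- function(m) sqrt(mean((m - s$truth$true_motion)^2))
  expect_lte(rms(m3), rms(m1))
})

test_that("motion correction inverts planted motion on the clean phantom", {
  spec <- fast_spec(sigma_thermal = 0, amp_cardiac = 0, amp_resp = 0,
                    amp_csf_puls = 0, amp_drift = 0, motion_sd_vox = 1.0,
                    motion_slice_jitter = 0)
  s <- render_subject(spec, seed = 23)
  m <- estimate_motion_slicewise(s$series, search_vox = 3)
  corr <- apply_motion_correction(s$series, m)
  cord <- s$truth$masks$cord
  sd_in <- function(v) {
    X <- matrix(v$data, length(cord), dim(v$data)[4])[cord, ]
    mean(apply(X, 1, sd))
  }
  expect_gt(sd_in(s$series) / sd_in(corr), 5)
})

test_that("applying a zero or integer trace is exact", {
  arr <- array(rnorm(10 * 10 * 2 * 4), c(10, 10, 2, 4))
  v <- volume_series(arr, c(1, 1, 1), 1)
  z0 <- array(0, c(2, 4, 2))
  expect_equal(apply_motion_correction(v, z0)$data, arr, tolerance = 1e-12)
  # pure integer shifts invert exactly away from the clamped edges
  m <- array(0, c(2, 4, 2)); m[, , 1] <- 2; m[, , 2] <- -1
  shifted <- v
  for (z in 1:2) for (t in 1:4)
    shifted$data[, , z, t] <- spinefc:::shift_image(arr[, , z, t], 2, -1)
  back <- apply_motion_correction(shifted, m)
  expect_equal(back$data[3:8, 3:8, , ], arr[3:8, 3:8, , ], tolerance = 1e-12)
  expect_error(apply_motion_correction(v, array(0, c(3, 4, 2))), "match")
})

test_that("cardiac phase interpolates linearly between detected peaks", {
  fs <- 100; t <- seq(0, 30, by = 1 / fs)
  pulse <- (0.5 + 0.5 * cos(2 * pi * t))^6    # peaks at integer seconds
  p <- physio_recording(pulse, fs, sin(2 * pi * 0.25 * t), fs,
                        volume_onsets_s = seq(0, 26, by = 2.6))
  expect_equal(cardiac_phase(p, 10.5), pi, tolerance = 0.05)
  expect_equal(cardiac_phase(p, 10), 0, tolerance = 0.05)
  # phantom trace: phase at planted peak times is ~0 (mod 2*pi)
  ph <- synth_physio(120, seed = 8)
  peaks <- attr(ph, "peak_times_s")
  mid <- peaks[peaks > 5 & peaks < 115]
  phi <- cardiac_phase(ph, mid)
  expect_lt(max(pmin(phi, 2 * pi - phi)), 0.05)
  flat <- physio_recording(rep(1, 3001), fs,
                           sin(2 * pi * 0.25 * t), fs, c(0, 2.6, 5.2))
  expect_error(cardiac_phase(flat, 1), "peaks")
})

test_that("respiratory phase equalises amplitude histogram with slope sign", {
  fs <- 25; t <- seq(0, 200, by = 1 / fs)
  p <- physio_recording((0.5 + 0.5 * cos(2 * pi * 1.1 * t))^4, fs,
                        sin(2 * pi * 0.25 * t), fs, seq(0, 190, by = 2.6))
  # at the respiratory maximum |phi| = pi
  tmax <- 9  # sin(2*pi*0.25*t) peaks at t = 1 + 4k
  expect_equal(abs(respiratory_phase(p, tmax)), pi, tolerance = 0.08)
  # at the mean amplitude on inhalation phi ~ +pi/2
  expect_equal(respiratory_phase(p, 4 / 0.25 + 1e-3), pi / 2,
               tolerance = 0.15)
  # time reversal flips the sign at interior points
  p_rev <- physio_recording(p$cardiac, fs, rev(p$respiratory), fs,
                            p$volume_onsets_s)
  q <- seq(20, 180, by = 3.1)
  a <- respiratory_phase(p, q)
  b <- respiratory_phase(p_rev, max(t) - q)
  # compare only where the slope is well away from its sign change
  interior <- abs(cos(2 * pi * 0.25 * q)) > 0.3 &
    abs(a) > 0.3 & abs(abs(a) - pi) > 0.3
  expect_true(all(sign(a[interior]) == -sign(b[interior])))
  flat <- physio_recording(p$cardiac, fs, rep(1, length(t)), fs,
                           p$volume_onsets_s)
  expect_error(respiratory_phase(flat, 1), "flat")
})

test_that("RETROICOR regressors span the planted physiological basis", {
  s <- cached("subj_default", render_subject(phantom_spec(), seed = 42))
  X <- retroicor_regressors(s$physio, s$physio$volume_onsets_s, order = 2)
  expect_identical(ncol(X), 8L)
  expect_lt(max(abs(colMeans(X))), 1e-12)
  # regress from a voxel whose physio term uses the same basis
  onsets <- s$physio$volume_onsets_s
  phi_c <- spinefc:::phase_from_peaks(s$truth$peak_times_s, onsets)
  planted <- 3 * cos(phi_c) - 2 * sin(2 * phi_c)
  set.seed(1)
  y <- planted + rnorm(length(onsets), sd = 0.1)
  res <- resid(lm(y ~ X))
  expect_lt(var(res), 0.05 * var(planted))
  # constant cardiac phase (volumes locked to the cardiac cycle) degenerates
  fs <- 100; t <- seq(0, 30, 1 / fs)
  locked <- physio_recording((0.5 + 0.5 * cos(2 * pi * t))^6, fs,
                             sin(2 * pi * 0.11 * t), fs, c(0.25, 1.25, 2.25))
  expect_error(retroicor_regressors(locked, c(0.25, 1.25, 2.25), order = 2L),
               "degenerate")
})

test_that("slicewise PCA recovers planted patterns and is orthonormal", {
  set.seed(31)
  nt <- 150
  u <- scale(matrix(rnorm(nt * 2), nt, 2))
  arr <- array(rnorm(12 * 12 * 2 * nt, sd = 1e-3), c(12, 12, 2, nt))
  mask <- array(FALSE, c(12, 12, 2)); mask[3:8, 3:8, 1] <- TRUE
  W <- matrix(rnorm(sum(mask) * 2), ncol = 2)
  planted <- W %*% t(u)                      # nvox x nt
  arr1 <- matrix(arr[, , 1, ], 144, nt)
  arr1[mask[, , 1], ] <- arr1[mask[, , 1], ] + planted
  arr[, , 1, ] <- array(arr1, c(12, 12, nt))
  v <- volume_series(arr, c(1, 1, 1), 1)
  pcs <- slicewise_pca_regressors(v, mask, k = 5)
  expect_null(pcs[[2]])
  cc <- cancor(pcs[[1]][, 1:2], u)$cor
  expect_gt(min(cc), 0.99)
  # orthogonality and ordering
  C <- cor(pcs[[1]])
  expect_lt(max(abs(C[upper.tri(C)])), 1e-10)
  expl <- attr(pcs[[1]], "explained")
  expect_true(all(diff(expl) <= 1e-12))
  # oracle: components match prcomp's scores up to sign
  X <- t(matrix(arr[, , 1, ], 144, nt)[mask[, , 1], ])
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  for (j in 1:5) {
    sc <- scale(pr$x[, j])
    expect_lt(min(sum((pcs[[1]][, j] - sc)^2),
                  sum((pcs[[1]][, j] + sc)^2)) / nt, 1e-8)
  }
})

test_that("nuisance design has the documented structure", {
  s <- cached("subj_default", render_subject(phantom_spec(), seed = 42))
  m <- estimate_motion_slicewise(s$series)
  moco <- apply_motion_correction(s$series, m)
  des <- build_nuisance_design(moco, s$physio, s$truth$masks, m,
                               study_config())
  expect_length(des, 14L)
  X <- des[[7]]
  expect_identical(ncol(X), 21L)           # 8 + 5 + 5 + 2 + intercept
  expect_true(all(c("retroicor_card_cos1", "csf_pc_1", "notspine_pc_5",
                    "motion_tx", "intercept") %in% colnames(X)))
  sds <- apply(X[, setdiff(colnames(X), "intercept")], 2, sd)
  expect_true(all(sds > 1e-10))
})

test_that("nuisance regression leaves residuals orthogonal to the design", {
  dn <- default_denoise()
  des <- dn$des; moco <- dn$moco
  den <- regress_nuisance(moco, des)
  z <- 7L
  Y <- t(spinefc:::slice_matrix(den, z))
  Yc <- sweep(Y, 2, colMeans(Y))
  X <- des[[z]][, setdiff(colnames(des[[z]]), "intercept")]
  cors <- abs(cor(X, Yc[, apply(Yc, 2, sd) > 0]))
  expect_lt(max(cors), 1e-8)
  # intercept-only design returns the input unchanged
  id_des <- lapply(1:14, function(z) cbind(intercept = rep(1, 200)))
  class(id_des) <- "nuisance_design"
  same <- regress_nuisance(moco, id_des)
  expect_equal(same$data, moco$data, tolerance = 1e-10)
})

test_that("CSF pulsation leaking into the cord is largely regressed out", {
  spec <- fast_spec()
  s <- render_subject(spec, seed = 25)
  m <- estimate_motion_slicewise(s$series)
  moco <- apply_motion_correction(s$series, m)
  des <- build_nuisance_design(moco, s$physio, s$truth$masks, m,
                               study_config())
  den <- regress_nuisance(moco, des)
  # variance of the projection onto the planted CSF patterns, cord voxels
  cord <- s$truth$masks$cord
  proj_var <- function(v, z) {
    X <- t(spinefc:::slice_matrix(v, z)[cord[, , z], ])
    X <- sweep(X, 2, colMeans(X))
    pc <- slicewise_pca_regressors(moco, s$truth$masks$csf, 2)[[z]]
    sum(qr.fitted(qr(pc), X)^2)
  }
  for (z in c(3L, 5L)) {
    before <- proj_var(moco, z); after <- proj_var(den, z)
    expect_lt(after, 0.2 * before)
  }
})

test_that("band-pass is selective and zero-phase", {
  nt <- 400; tr <- 2.6; tt <- (0:(nt - 1)) * tr
  keep <- sin(2 * pi * 0.05 * tt)
  kill <- sin(2 * pi * 0.15 * tt)
  arr <- array(0, c(2, 2, 1, nt))
  arr[1, 1, 1, ] <- 100 + keep
  arr[2, 1, 1, ] <- 100 + kill
  arr[1, 2, 1, ] <- 100 + keep + kill
  arr[2, 2, 1, ] <- 100
  v <- bandpass(volume_series(arr, c(1, 1, 1), tr), 0.01, 0.10)
  a_keep <- fft_amp(v$data[1, 1, 1, ], 0.05, 1 / tr)
  a_kill <- fft_amp(v$data[2, 1, 1, ], 0.15, 1 / tr)
  expect_gt(a_keep, 0.95)
  expect_lt(a_kill, 0.10)
  # temporal mean restored
  expect_equal(mean(v$data[1, 1, 1, ]), 100, tolerance = 1e-6)
  # zero phase: cross-correlation of the in-band component peaks at lag 0
  ccf_out <- ccf(v$data[1, 1, 1, ] - mean(v$data[1, 1, 1, ]), keep,
                 lag.max = 10, plot = FALSE)
  expect_identical(ccf_out$lag[which.max(ccf_out$acf)], 0)
  expect_error(bandpass(volume_series(arr, c(1, 1, 1), tr), 0.01, 0.2),
               "Nyquist")
})

test_that("TSNR follows its definition and stages increase on the phantom", {
  arr <- array(0, c(2, 2, 2, 50))
  set.seed(41)
  base <- rnorm(50)
  arr[1, 1, 1, ] <- 100 + 25 * scale(base)   # mu 100, sd 25
  arr[2, 2, 2, ] <- 7                        # constant: sd = 0
  arr[1, 2, 1, ] <- rnorm(50, 10, 1)
  arr[2, 1, 1, ] <- rnorm(50, 10, 1)
  arr[1, 1, 2, ] <- rnorm(50, 10, 1)
  v <- volume_series(arr, c(1, 1, 1), 1)
  cord <- array(TRUE, c(2, 2, 2))
  gm <- array(FALSE, c(2, 2, 2)); gm[1, 1, 1] <- TRUE
  csf <- array(FALSE, c(2, 2, 2))
  masks <- list(cord = cord, gm = gm, csf = csf, notspine = !cord)
  tm <- tsnr(v, v, masks, "after_moco", central_slices = 2L)
  expect_equal(tm$map[1, 1, 1], 4, tolerance = 1e-6)
  expect_true(is.na(tm$map[2, 2, 2]))
  expect_equal(tm$summary, 4, tolerance = 1e-6)
  # full pipeline monotonicity on the default phantom
  s <- cached("subj_default", render_subject(phantom_spec(), seed = 42))
  res <- cached("analysis_default", analyze_subject(s))
  expect_gt(res$denoise$tsnr_denoise$summary,
            res$denoise$tsnr_moco$summary)
})

test_that("correlations are insensitive to the regress/filter order", {
  dn <- default_denoise()
  s <- dn$s; moco <- dn$moco; des <- dn$des
  cfg <- study_config()
  # default order: regress then filter
  den1 <- bandpass(regress_nuisance(moco, des), cfg$bandpass_lo_hz,
                   cfg$bandpass_hi_hz)
  # alternative: filter data and regressors, then regress
  mocof <- bandpass(moco, cfg$bandpass_lo_hz, cfg$bandpass_hi_hz)
  ba <- spinefc:::butter_band(cfg$bandpass_lo_hz, cfg$bandpass_hi_hz,
                              1 / s$series$tr_s)
  desf <- lapply(des, function(X) {
    Xf <- spinefc:::filtfilt_mat(ba$b, ba$a, X[, colnames(X) != "intercept"])
    colnames(Xf) <- setdiff(colnames(X), "intercept")
    cbind(Xf, intercept = 1)
  })
  class(desf) <- "nuisance_design"
  den2 <- regress_nuisance(mocof, desf)
  q <- partition_gm_quadrants(s$truth$masks$gm)
  r1 <- network_correlations(roi_timeseries(den1, q))$summary
  r2 <- network_correlations(roi_timeseries(den2, q))$summary
  # the orders differ by a small degrees-of-freedom effect: the filtered
  # design spends its ~21 columns inside ~90 in-band dimensions instead of
  # ~199 full-band ones, so slightly more in-band signal is absorbed;
  # see the methods vignette for the variance accounting
  expect_lt(max(abs(r1 - r2)), 0.04)
  expect_lt(abs(mean(r1 - r2)), 0.025)
})
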