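test_that("in-plane registration recovers planted transforms", {
  geom <- make_geometry(fast_spec())
  base <- array(0, dim(geom$masks$cord))
  base[geom$masks$cord] <- 900
  base[geom$masks$gm] <- 1100
  base[geom$masks$csf] <- 1300
  for (z in seq_len(dim(base)[3]))
    base[, , z] <- spinefc:::blur_image(base[, , z], 0.8)
  set.seed(81)
  base <- base + array(rnorm(length(base), sd = 5), dim(base))
  # identical images give the identity transform
  tf0 <- register_inplane(base, base)
  expect_lt(max(abs(tf0$tx), abs(tf0$ty), abs(tf0$scale - 1)), 1e-3)
  # planted translation
  mov <- base
  for (z in seq_len(dim(base)[3]))
    mov[, , z] <- spinefc:::shift_image(base[, , z], 0.8, -0.5)
  tf <- register_inplane(mov, base)
  expect_lt(max(abs(tf$tx - (-0.8))), 0.1)
  expect_lt(max(abs(tf$ty - 0.5)), 0.1)
  # planted 5% scale
  mov2 <- base
  for (z in seq_len(dim(base)[3]))
    mov2[, , z] <- spinefc:::transform_image(base[, , z], 0, 0, 1.05)
  tf2 <- register_inplane(mov2, base)
  expect_lt(max(abs(tf2$scale - 1 / 1.05)), 0.0105)
})

test_that("cropping centres on the lumbar enlargement", {
  geom <- make_geometry(phantom_spec())
  v <- volume_series(array(rnorm(48 * 48 * 14 * 4), c(48, 48, 14, 4)),
                     c(0.43, 0.43, 5), 2.6)
  vc <- crop_to_enlargement(v, geom$masks$cord, 5)
  expect_identical(attr(vc, "slice_range"), 4:8)   # enlargement-centred crop
  expect_identical(dim(vc)[3], 5L)
  v_all <- crop_to_enlargement(v, geom$masks$cord, 14)
  expect_equal(v_all$data, v$data)
  expect_error(crop_to_enlargement(v, geom$masks$cord, 15), "exceeds")
})

test_that("subject PCA reduction is lossless at full rank and ordered", {
  set.seed(82)
  nt <- 40L
  arr <- array(rnorm(8 * 8 * 2 * nt), c(8, 8, 2, nt))
  v <- volume_series(arr, c(1, 1, 1), 1)
  mask <- array(runif(128) > 0.4, c(8, 8, 2))
  R <- subject_pca_reduce(v, mask, p1 = nt - 1L)
  # reconstruction through the stored temporal basis
  X <- matrix(arr, 128, nt)[mask, ]
  X <- X - rowMeans(X); X <- X / sqrt(rowMeans(X^2))
  X <- sweep(X, 2, colMeans(X))
  Xhat <- R %*% t(attr(R, "basis"))
  expect_lt(max(abs(Xhat - X)), 1e-8)
  expect_true(all(diff(attr(R, "explained")) <= 1e-12))
  # identical subjects give identical reductions
  R2 <- subject_pca_reduce(v, mask, p1 = nt - 1L)
  expect_identical(R, R2)
  expect_error(subject_pca_reduce(v, array(FALSE, c(8, 8, 2))), "empty")
})

test_that("Infomax separates planted super-Gaussian sources", {
  set.seed(83)
  n <- 3000L
  S <- matrix(0, 3, n)
  for (i in 1:3) S[i, sample.int(n, 200)] <- rnorm(200, sd = 3)
  S <- S + 0.05 * matrix(rnorm(3 * n), 3)
  A <- matrix(rnorm(9), 3, 3)
  fit <- infomax_ica(A %*% S, 3, seed = 7)
  P <- cor(t(fit$sources), t(S))
  expect_lt(amari_distance(P), 0.05)
  expect_gt(min(apply(abs(P), 2, max)), 0.99)
  # determinism under the seed
  fit2 <- infomax_ica(A %*% S, 3, seed = 7)
  expect_identical(fit$sources, fit2$sources)
  # single component reduces to the leading principal direction
  fit1 <- infomax_ica(A %*% S, 1, seed = 7)
  pc1 <- prcomp(t(A %*% S))$x[, 1]
  expect_gt(abs(cor(fit1$sources[1, ], pc1)), 0.999)
  # sign convention: peak-magnitude sample is positive
  expect_true(all(apply(fit$sources, 1,
                        function(s) s[which.max(abs(s))] > 0)))
})

test_that("component z-maps are standardised, nested and thresholded", {
  mask <- array(TRUE, c(5, 5, 2))
  set.seed(84)
  zm <- matrix(rnorm(3 * 50), 3, 50)
  zm[1, 1] <- 30                         # one extreme voxel
  res <- structure(list(zmaps = zm, mask = mask, n_components = 3L),
                   class = "group_ica_result")
  out4 <- component_zmaps(res, 4)
  out7 <- component_zmaps(res, 7)
  # nesting: the z>=7 region is inside the z>=4 region
  expect_true(all(out4$binary[out7$binary]))
  # a map whose maximum z is 3.9 thresholds to empty at 4
  sd0 <- sd(zm[2, ]); m0 <- mean(zm[2, ])
  zcap <- (zm[2, ] - m0) / sd0
  expect_lt(max(zcap), 3.9 + 1)          # sanity on the construction
  capped <- res; capped$zmaps[2, ] <- m0 + sd0 * zcap * (3.9 / max(zcap))
  expect_identical(sum(component_zmaps(capped, 4)$binary[, , , 2]), 0L)
  # standardisation within the mask
  expect_equal(mean(out4$signed[, , , 3]), 0, tolerance = 1e-12)
  expect_equal(sd(out4$signed[, , , 3]), 1, tolerance = 1e-6)
})

test_that("planted components are classified by tissue, subtype and side", {
  spec <- fast_spec()
  geom <- make_geometry(spec)
  rng <- 2:6
  masks <- mask_set(geom$masks$cord[, , rng], geom$masks$gm[, , rng],
                    geom$masks$csf[, , rng], geom$masks$notspine[, , rng])
  quads <- partition_gm_quadrants(masks$gm)
  d <- dim(masks$gm)
  mk_signed <- function(b) { s <- array(0, d); s[b] <- 5; s }
  cfg <- study_config()
  # confined to the left ventral horn
  b_lv <- array(FALSE, d); b_lv[, , 3][geom$quadrants[, , 4] == 1L] <- TRUE
  lab <- classify_component(b_lv, mk_signed(b_lv), masks, quads, cfg)
  expect_identical(lab$tissue, "GM")
  expect_identical(lab$subtype, "ventral")
  expect_identical(lab$side, "left")
  # both dorsal horns on one slice: bilateral dorsal
  b_d <- array(FALSE, d)
  b_d[, , 3][geom$quadrants[, , 4] %in% c(3L, 4L)] <- TRUE
  lab2 <- classify_component(b_d, mk_signed(b_d), masks, quads, cfg)
  expect_identical(lab2$tissue, "GM")
  expect_identical(lab2$subtype, "dorsal")
  expect_identical(lab2$side, "bilateral")
  expect_identical(lab2$slice_extent, 1L)
  # mostly in CSF/background: noise
  b_n <- array(FALSE, d); b_n[, , 2][masks$csf[, , 2]] <- TRUE
  lab3 <- classify_component(b_n, mk_signed(b_n), masks, quads, cfg)
  expect_identical(lab3$tissue, "noise")
  # in cord but not GM-dominant: white matter
  b_wm <- array(FALSE, d)
  wm2 <- masks$cord[, , 3] & !masks$gm[, , 3]
  b_wm[, , 3][which(wm2)[1:40]] <- TRUE
  lab4 <- classify_component(b_wm, mk_signed(b_wm), masks, quads, cfg)
  expect_identical(lab4$tissue, "WM")
})

test_that("Dice overlap and matching follow their definitions", {
  a <- array(FALSE, c(4, 4, 2)); a[1:2, , 1] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, c(4, 4, 2)); b[3:4, , 2] <- TRUE
  expect_equal(dice(a, b), 0)
  # |a| = |b| = 100, overlap 50 -> 0.5
  x <- array(FALSE, c(20, 10, 1)); x[1:10, , 1] <- TRUE
  y <- array(FALSE, c(20, 10, 1)); y[6:15, , 1] <- TRUE
  expect_equal(dice(x, y), 0.5)
  expect_error(dice(b & FALSE, b & FALSE), "empty")
  # matching recovers a planted permutation (vs brute-force assignment)
  set.seed(85)
  maps <- lapply(1:5, function(i) {
    m <- array(FALSE, c(10, 10, 1)); m[sample.int(100, 20)] <- TRUE; m
  })
  perm <- sample(5)
  tab <- match_components(maps, maps[perm])
  expect_identical(nrow(tab), 5L)
  expect_true(all(tab$dice == 1))
  expect_identical(order(perm)[tab$component_a], tab$component_b)
  # brute force over all permutations confirms optimality on noisy sets
  maps_b <- lapply(1:4, function(i) {
    m <- array(FALSE, c(10, 10, 1)); m[sample.int(100, 25)] <- TRUE; m
  })
  D <- outer(1:4, 1:4, Vectorize(function(i, j) dice(maps[[i]], maps_b[[j]])))
  tab2 <- match_components(maps[1:4], maps_b, dice_floor = 0)
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, anyDuplicated) == 0, ]
  best <- max(apply(perms, 1, function(p) sum(D[cbind(1:4, p)])))
  expect_equal(sum(tab2$dice), best, tolerance = 1e-12)
  # unequal set sizes match at most the smaller count
  tab3 <- match_components(maps[1:3], maps_b[1:2], dice_floor = 0)
  expect_lte(nrow(tab3), 2L)
})

test_that("split-half analysis on identical halves reproduces itself", {
  cfg <- study_config(subject_pca_dims = 25L, ica_crop_slices = 5L,
                      z_thresh = 1.0)
  co <- make_cohort(2, base = fast_spec(), seed = 91)
  subs <- list(); masks <- list()
  for (i in 1:2) {
    s <- render_subject(co$specs[[i]])
    a <- analyze_subject(s, cfg)
    subs[[i]] <- a$denoise$denoised
    masks[[i]] <- s$truth$masks
  }
  # the same two subjects form both halves
  res <- split_half_analysis(subs[c(1, 2, 1, 2)],
                             masks[c(1, 2, 1, 2)],
                             split = c(1L, 1L, 2L, 2L),
                             n_components = 4L, analysis_mask = "gm",
                             config = cfg, seed = 19)
  expect_gt(res$summary["mean_dice_gm"], 0.95)
  expect_identical(unname(res$summary["n_matched"]),
                   as.numeric(sum(res$matches$matched)))
})
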