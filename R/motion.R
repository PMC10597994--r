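#' Estimate slicewise in-plane motion
#'
#' For every slice, the 2D translation of each volume that minimises the
#' sum of squared intensity differences to the slice's temporal mean is
#' found by an exhaustive sub-voxel grid search with quadratic peak
#' refinement, then refined once against the corrected mean. Estimates are
#' finally smoothed across slices with a moving average of width
#' `reg_width` — the regularisation along the rostro-caudal axis.
#'
#' @param v a [volume_series()] with at least two volumes.
#' @param reg_width moving-average width (slices) for the rostro-caudal
#'   regularisation; 1 disables it.
#' @param search_vox half-width of the translation search (voxels).
#' @param step_vox grid spacing of the search; sub-grid translations are
#'   recovered by Gauss-Newton least-squares refinement.
#' @param time_smooth window (volumes) of the local-quadratic
#'   (Savitzky-Golay) smoother applied to the estimates, exploiting the
#'   temporal smoothness of physiological motion without attenuating it;
#'   1 disables it.
#' @return a `motion_trace`: array `(slice, volume, tx/ty)` in voxels,
#'   relative to the slice temporal mean (attribute `reference`).
#' @export
estimate_motion_slicewise <- function(v, reg_width = 3L, search_vox = 1.5,
                                      step_vox = 0.25, time_smooth = 7L) {
  stopifnot(inherits(v, "volume_series"))
  d <- dim(v$data)
  if (d[4] < 2L) stop("need at least 2 volumes", call. = FALSE)
  nz <- d[3]; nt <- d[4]
  m <- array(0, c(nz, nt, 2L))
  for (z in seq_len(nz)) {
    S <- slice_matrix(v, z)
    if (stats::sd(S) == 0 || all(abs(S - mean(S)) < 1e-12)) {
      warning("slice ", z, " is empty; motion set to zero")
      next
    }
    ref <- matrix(rowMeans(S), d[1], d[2])
    est <- translation_grid_search(S, ref, d[1], d[2], search_vox, step_vox)
    # one refinement pass against the corrected mean
    Sc <- S
    for (t in seq_len(nt)) {
      img <- matrix(S[, t], d[1], d[2])
      Sc[, t] <- shift_image(img, -est[t, 1], -est[t, 2])
    }
    ref2 <- matrix(rowMeans(Sc), d[1], d[2])
    est2 <- translation_grid_search(S, ref2, d[1], d[2], search_vox, step_vox)
    if (time_smooth > 1L)
      for (ax in 1:2) est2[, ax] <- sg_smooth(est2[, ax], time_smooth)
    m[z, , ] <- est2
  }
  if (reg_width > 1L && nz > 1L) {
    half <- (as.integer(reg_width) - 1L) %/% 2L
    sm <- m
    for (z in seq_len(nz)) {
      win <- max(1L, z - half):min(nz, z + half)
      sm[z, , ] <- apply(m[win, , , drop = FALSE], c(2, 3), mean)
    }
    m <- sm
  }
  structure(m, class = "motion_trace", reference = "temporal mean")
}

# SSD of every volume against a bank of shifted references (one matrix
# product per slice), followed by Gauss-Newton (Lucas-Kanade) sub-voxel
# refinement; returns nt x 2 translations
translation_grid_search <- function(S, ref, nx, ny, search_vox, step_vox) {
  taus <- seq(-search_vox, search_vox, by = step_vox)
  ng <- length(taus)
  Rk <- matrix(0, nx * ny, ng * ng)
  k <- 0L
  grid <- matrix(0, ng * ng, 2L)
  for (jy in seq_len(ng)) for (jx in seq_len(ng)) {
    k <- k + 1L
    Rk[, k] <- shift_image(ref, taus[jx], taus[jy])
    grid[k, ] <- c(taus[jx], taus[jy])
  }
  ssd <- -2 * crossprod(Rk, S) + colSums(Rk^2)   # + const per volume
  best <- apply(ssd, 2, which.min)
  est <- grid[best, , drop = FALSE]
  for (pass in 1:2)
    est <- lk_refine(S, ref, nx, ny, est, max_step = step_vox)
  est
}

# one Gauss-Newton step towards the least-squares translation, vectorised
# over all volumes sharing the same current estimate
lk_refine <- function(S, ref, nx, ny, est, max_step = 0.25) {
  keys <- paste(round(est[, 1], 6), round(est[, 2], 6))
  for (key in unique(keys)) {
    sel <- which(keys == key)
    tau <- est[sel[1], ]
    refw <- shift_image(ref, tau[1], tau[2])
    gx <- (refw[c(2:nx, nx), ] - refw[c(1, 1:(nx - 1)), ]) / 2
    gy <- (refw[, c(2:ny, ny)] - refw[, c(1, 1:(ny - 1))]) / 2
    G <- cbind(as.vector(gx), as.vector(gy))
    M <- crossprod(G)
    if (rcond(M) < 1e-12) next
    resid <- S[, sel, drop = FALSE] - as.vector(refw)
    delta <- -solve(M, crossprod(G, resid))        # 2 x |sel|
    delta <- pmin(pmax(delta, -max_step), max_step)
    est[sel, ] <- est[sel, , drop = FALSE] + t(delta)
  }
  est
}

#' Apply a slicewise motion correction
#'
#' Resamples every slice-volume by the negated estimated translation with
#' bilinear interpolation; samples falling outside the grid take edge
#' values.
#'
#' @param v a [volume_series()].
#' @param m a `motion_trace` from [estimate_motion_slicewise()] matching
#'   `v`'s slices and volumes.
#' @return the corrected [volume_series()].
#' @export
apply_motion_correction <- function(v, m) {
  stopifnot(inherits(v, "volume_series"))
  d <- dim(v$data)
  dm <- dim(m)
  if (dm[1] != d[3] || dm[2] != d[4])
    stop("motion trace shape does not match series", call. = FALSE)
  out <- v$data
  for (z in seq_len(d[3]))
    for (t in seq_len(d[4]))
      if (m[z, t, 1] != 0 || m[z, t, 2] != 0)
        out[, , z, t] <- shift_image(v$data[, , z, t],
                                     -m[z, t, 1], -m[z, t, 2])
  volume_series(out, v$voxel_mm, v$tr_s, space_tag = v$space_tag)
}


# Savitzky-Golay local-quadratic smoother with shrinking edge windows
sg_smooth <- function(y, w = 7L, deg = 2L) {
  n <- length(y)
  if (n <= deg + 1L) return(y)
  half <- as.integer(w) %/% 2L
  tt <- -half:half
  X <- outer(tt, 0:deg, "^")
  cc <- solve(crossprod(X), t(X))[1, ]     # centre-point coefficients
  out <- y
  if (n >= w)
    for (t in (half + 1L):(n - half))
      out[t] <- sum(cc * y[(t - half):(t + half)])
  for (t in c(seq_len(min(half, n)), seq.int(max(1L, n - half + 1L), n))) {
    lo <- max(1L, t - half); hi <- min(n, t + half)
    if (hi - lo < deg + 1L) next
    ttt <- (lo:hi) - t
    Xe <- outer(ttt, 0:deg, "^")
    out[t] <- qr.solve(Xe, y[lo:hi])[1]
  }
  out
}
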