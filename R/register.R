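#' Slicewise in-plane registration to a target image
#'
#' Estimates, per slice, the 2D translation and isotropic scale that best
#' align (least-squares on intensities) a subject's mean functional image
#' with a target subject's mean image. A stand-in for nonlinear in-plane
#' registration, sufficient for subjects differing by small rigid/scale
#' changes.
#'
#' @param moving_mean,target_mean 3D arrays with the same slice count.
#' @return a data frame of class `inplane_transform` with columns
#'   `slice, tx, ty, scale`.
#' @export
register_inplane <- function(moving_mean, target_mean) {
  dm <- dim(moving_mean); dt <- dim(target_mean)
  stopifnot(length(dm) == 3L, length(dt) == 3L)
  if (dm[3] != dt[3]) stop("slice counts differ", call. = FALSE)
  nz <- dm[3]
  out <- data.frame(slice = seq_len(nz), tx = 0, ty = 0, scale = 1)
  for (z in seq_len(nz)) {
    mov <- moving_mean[, , z]; tgt <- target_mean[, , z]
    if (stats::sd(mov) == 0 || stats::sd(tgt) == 0)
      stop("empty slice ", z, call. = FALSE)
    obj <- function(p) {
      s <- exp(p[3])
      sum((transform_image(mov, p[1], p[2], s) - tgt)^2)
    }
    # coarse translation initialisation on a +/- 2 voxel grid
    taus <- seq(-2, 2, by = 0.5)
    best <- c(0, 0); bv <- Inf
    for (ty in taus) for (tx in taus) {
      val <- sum((shift_image(mov, tx, ty) - tgt)^2)
      if (val < bv) { bv <- val; best <- c(tx, ty) }
    }
    fit <- stats::optim(c(best, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    out$tx[z] <- fit$par[1]; out$ty[z] <- fit$par[2]
    out$scale[z] <- exp(fit$par[3])
  }
  class(out) <- c("inplane_transform", "data.frame")
  out
}

#' Apply an in-plane transform to a 4D series
#'
#' Resamples every slice-volume with the slice's translation + scale using
#' bilinear interpolation.
#'
#' @param v a [volume_series()].
#' @param tf an `inplane_transform` from [register_inplane()].
#' @return the resampled [volume_series()] tagged `"target-registered"`.
#' @export
apply_inplane_transform <- function(v, tf) {
  d <- dim(v$data)
  if (nrow(tf) != d[3]) stop("transform slice count mismatch", call. = FALSE)
  out <- v$data
  for (z in seq_len(d[3]))
    for (t in seq_len(d[4]))
      out[, , z, t] <- transform_image(v$data[, , z, t], tf$tx[z], tf$ty[z],
                                       tf$scale[z])
  volume_series(out, v$voxel_mm, v$tr_s, space_tag = "target-registered")
}

#' Crop a series to the slices around the lumbar enlargement
#'
#' Keeps `n_slices` centred on the slice of maximal cord cross-sectional
#' area (the anatomical definition of the enlargement), re-indexed from 1.
#'
#' @param v a [volume_series()].
#' @param cord_mask logical 3D cord mask used to locate the enlargement.
#' @param n_slices slices to keep.
#' @return the cropped [volume_series()] with attribute `slice_range`
#'   (original 1-based indices kept).
#' @export
crop_to_enlargement <- function(v, cord_mask, n_slices = 5L) {
  d <- dim(v$data)
  if (n_slices > d[3])
    stop("n_slices (", n_slices, ") exceeds available slices (", d[3], ")",
         call. = FALSE)
  area <- apply(cord_mask, 3, sum)
  centre <- which.max(area)
  half_lo <- (n_slices - 1L) %/% 2L
  lo <- min(max(centre - half_lo, 1L), d[3] - n_slices + 1L)
  rng <- seq(lo, lo + n_slices - 1L)
  out <- volume_series(v$data[, , rng, , drop = FALSE], v$voxel_mm, v$tr_s,
                       space_tag = v$space_tag)
  attr(out, "slice_range") <- rng
  out
}
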