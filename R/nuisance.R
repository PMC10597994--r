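#' Slicewise principal-component nuisance time-courses
#'
#' CompCor-style noise regressors: for each slice, every in-mask voxel
#' time-series is centred and the top-`k` temporal principal components
#' (unit variance, ordered by explained variance) are returned.
#'
#' @param v a [volume_series()].
#' @param mask logical 3D array on `v`'s grid (e.g. CSF or not-spine).
#' @param k components per slice.
#' @return a list with one element per slice: `n_volumes x k` matrix with
#'   attribute `explained` (variance fractions), or `NULL` for slices where
#'   the mask is empty. Slices with fewer than `k` in-mask voxels return as
#'   many components as voxels, with a warning.
#' @export
slicewise_pca_regressors <- function(v, mask, k = 5L) {
  stopifnot(inherits(v, "volume_series"))
  d <- dim(v$data)
  if (!all(dim(mask) == d[1:3]))
    stop("mask grid does not match series", call. = FALSE)
  if (d[4] <= k) stop("need more volumes than components", call. = FALSE)
  out <- vector("list", d[3])
  for (z in seq_len(d[3])) {
    sel <- as.vector(mask[, , z])
    if (!any(sel)) { out[z] <- list(NULL); next }
    X <- slice_matrix(v, z)[sel, , drop = FALSE]    # nvox x nt
    X <- X - rowMeans(X)
    kz <- min(k, nrow(X))
    if (kz < k)
      warning("slice ", z, ": only ", nrow(X),
              " in-mask voxels; returning ", kz, " components")
    if (nrow(X) <= ncol(X)) {
      # few voxels: eigen-decompose the spatial covariance
      e <- eigen(tcrossprod(X), symmetric = TRUE)
      evals <- pmax(e$values, 0)
      comp <- crossprod(X, e$vectors[, seq_len(kz), drop = FALSE])
    } else {
      e <- eigen(crossprod(X), symmetric = TRUE)    # nt x nt
      evals <- pmax(e$values, 0)
      comp <- e$vectors[, seq_len(kz), drop = FALSE] *
        rep(sqrt(evals[seq_len(kz)]), each = ncol(X))
    }
    comp <- sweep(comp, 2, colMeans(comp))
    # exact orthogonality of the centred components
    Q <- qr.Q(qr(comp))
    for (j in seq_len(ncol(Q)))
      if (sum(Q[, j] * comp[, j]) < 0) Q[, j] <- -Q[, j]
    comp <- Q
    sdv <- apply(comp, 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    comp <- sweep(comp, 2, sdv, "/")
    colnames(comp) <- paste0("pc_", seq_len(kz))
    attr(comp, "explained") <- evals[seq_len(kz)] / sum(evals)
    out[[z]] <- comp
  }
  out
}

#' Assemble the per-slice nuisance design
#'
#' Combines the RETROICOR Fourier regressors, the slicewise CSF and
#' not-spine principal components, the slice's own motion parameters and
#' an intercept into one labelled design matrix per slice (21 columns with
#' the defaults).
#'
#' @param v the motion-corrected [volume_series()].
#' @param physio a [physio_recording()].
#' @param masks a [mask_set()].
#' @param motion a `motion_trace` from [estimate_motion_slicewise()].
#' @param config a [study_config()].
#' @return a list of class `nuisance_design`, one design matrix per slice.
#' @export
build_nuisance_design <- function(v, physio, masks, motion,
                                  config = study_config()) {
  retro <- retroicor_regressors(physio, physio$volume_onsets_s,
                                order = config$retroicor_order)
  csf_pc <- slicewise_pca_regressors(v, masks$csf, config$n_pca_nuisance)
  nsp_pc <- slicewise_pca_regressors(v, masks$notspine,
                                     config$n_pca_nuisance)
  nz <- dim(v$data)[3]; nt <- dim(v$data)[4]
  out <- vector("list", nz)
  for (z in seq_len(nz)) {
    cs <- csf_pc[[z]]
    if (!is.null(cs)) colnames(cs) <- paste0("csf_", colnames(cs))
    np <- nsp_pc[[z]]
    if (!is.null(np)) colnames(np) <- paste0("notspine_", colnames(np))
    mo <- cbind(motion_tx = motion[z, , 1] - mean(motion[z, , 1]),
                motion_ty = motion[z, , 2] - mean(motion[z, , 2]))
    X <- cbind(retro, cs, np, mo, intercept = rep(1, nt))
    keep <- c(apply(X[, -ncol(X), drop = FALSE], 2, stats::sd) > 1e-10, TRUE)
    if (!all(keep))
      warning("slice ", z, ": dropping constant design columns: ",
              paste(colnames(X)[!keep], collapse = ", "))
    out[[z]] <- X[, keep, drop = FALSE]
  }
  class(out) <- "nuisance_design"
  out
}

#' Regress the nuisance design out of every voxel
#'
#' Ordinary least squares per voxel against the voxel's slice design; the
#' residual is returned with the voxel temporal mean restored so that TSNR
#' stays defined. Collinear design columns (condition number beyond the
#' configured limit) are dropped with a warning.
#'
#' @param v a [volume_series()].
#' @param design a `nuisance_design` from [build_nuisance_design()], one
#'   matrix per slice.
#' @param collinearity_cond condition-number limit.
#' @return the denoised [volume_series()].
#' @export
regress_nuisance <- function(v, design, collinearity_cond = 1e8) {
  stopifnot(inherits(v, "volume_series"))
  d <- dim(v$data)
  if (length(design) != d[3])
    stop("design must have one matrix per slice", call. = FALSE)
  out <- v$data
  for (z in seq_len(d[3])) {
    X <- design[[z]]
    if (is.null(X)) next
    if (nrow(X) != d[4]) stop("design rows != volumes on slice ", z,
                              call. = FALSE)
    sv <- svd(scale(X, center = FALSE,
                    scale = sqrt(colSums(X^2))), nu = 0, nv = 0)$d
    if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > collinearity_cond) {
      qrX <- qr(X)
      keep <- qrX$pivot[seq_len(qrX$rank)]
      warning("slice ", z, ": dropping collinear design columns: ",
              paste(setdiff(colnames(X), colnames(X)[keep]),
                    collapse = ", "))
      X <- X[, sort(keep), drop = FALSE]
    }
    Y <- t(slice_matrix(v, z))                    # nt x nvox
    mu <- colMeans(Y)
    qrX <- qr(X)
    resid <- Y - X %*% qr.coef(qrX, Y)
    out[, , z, ] <- array(t(resid + rep(mu, each = d[4])),
                          c(d[1], d[2], d[4]))
  }
  volume_series(out, v$voxel_mm, v$tr_s, space_tag = v$space_tag)
}

#' Temporal band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth filtering, order 2 per pass,
#' applied to every voxel time-series; the voxel temporal mean is restored
#' afterwards.
#'
#' @param v a [volume_series()].
#' @param lo_hz,hi_hz cut-off frequencies; `hi_hz` must be below the
#'   Nyquist frequency `1/(2*tr_s)`.
#' @return the filtered [volume_series()].
#' @export
bandpass <- function(v, lo_hz = 0.01, hi_hz = 0.10) {
  stopifnot(inherits(v, "volume_series"))
  fs <- 1 / v$tr_s
  ba <- butter_band(lo_hz, hi_hz, fs, order = 2L)
  d <- dim(v$data)
  out <- v$data
  for (z in seq_len(d[3])) {
    Y <- t(slice_matrix(v, z))
    mu <- colMeans(Y)
    Yf <- filtfilt_mat(ba$b, ba$a, Y)
    Yf <- sweep(Yf, 2, colMeans(Yf))   # exact zero-mean residual
    out[, , z, ] <- array(t(Yf + rep(mu, each = d[4])), c(d[1], d[2], d[4]))
  }
  volume_series(out, v$voxel_mm, v$tr_s, space_tag = v$space_tag)
}

#' Temporal signal-to-noise ratio map and gray-matter summary
#'
#' Voxelwise TSNR: temporal mean of `mean_source` over temporal SD of
#' `fluctuation_source`. For the `after_moco` stage both sources are the
#' motion-corrected series; for `after_denoise` the mean comes from the
#' motion-corrected series and the SD from the denoised, filtered
#' residual. Voxels with zero temporal SD are masked out (NA). The subject
#' summary is the mean over gray matter in the central slices.
#'
#' @param mean_source,fluctuation_source [volume_series()] objects on the
#'   same grid.
#' @param masks a [mask_set()].
#' @param stage label, `"after_moco"` or `"after_denoise"`.
#' @param central_slices number of central slices for the summary.
#' @return an object of class `tsnr_map`: list with the 3D `map`, `stage`
#'   and gray-matter `summary`.
#' @export
tsnr <- function(mean_source, fluctuation_source, masks,
                 stage = c("after_moco", "after_denoise"),
                 central_slices = 10L) {
  stage <- match.arg(stage)
  d <- dim(mean_source$data)
  if (!all(dim(fluctuation_source$data) == d))
    stop("sources are not on the same grid", call. = FALSE)
  nvox <- prod(d[1:3])
  M <- matrix(mean_source$data, nvox, d[4])
  F <- matrix(fluctuation_source$data, nvox, d[4])
  mu <- rowMeans(M)
  sdv <- sqrt(pmax(rowMeans(F^2) - rowMeans(F)^2, 0) * d[4] / (d[4] - 1))
  tsnr_v <- ifelse(sdv > 1e-10, mu / sdv, NA_real_)
  map <- array(tsnr_v, d[1:3])
  cz <- central_slice_range(d[3], central_slices)
  sel <- masks$gm
  sel[, , setdiff(seq_len(d[3]), cz)] <- FALSE
  vals <- map[sel]
  structure(list(map = map, stage = stage,
                 summary = mean(vals, na.rm = TRUE),
                 n_voxels = sum(!is.na(vals))),
            class = "tsnr_map")
}

#' @export
print.tsnr_map <- function(x, ...) {
  cat(sprintf("<tsnr_map> stage %s, GM summary %.2f over %d voxels\n",
              x$stage, x$summary, x$n_voxels))
  invisible(x)
}

# central n slices of nz: drop (nz - n)/2 from each end, caudal end first
central_slice_range <- function(nz, n_central) {
  n_central <- min(n_central, nz)
  lo <- floor((nz - n_central) / 2) + 1L
  seq(lo, lo + n_central - 1L)
}
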