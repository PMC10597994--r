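NETWORKS <- data.frame(
  network = c("VV", "DD", "VD_ipsi_L", "VD_ipsi_R",
              "VD_contra_LVRD", "VD_contra_RVLD"),
  a = c("LV", "LD", "LV", "RV", "LV", "RV"),
  b = c("RV", "RD", "LD", "RD", "RD", "LD"),
  stringsAsFactors = FALSE)

#' Partition a gray-matter mask into horn quadrants
#'
#' For every slice, the GM centre of mass bisects the mask vertically and
#' horizontally; the three voxel columns nearest the vertical split are
#' excluded (central commissure) along with the voxel row at the
#' horizontal split (separating ventral from dorsal GM); when the centre
#' of mass falls exactly between two columns the band widens by one so the
#' exclusion stays mirror-symmetric. Remaining GM
#' voxels are labelled left/right x ventral/dorsal. Slices where any
#' quadrant ends up empty are flagged and excluded from network averaging.
#'
#' @param gm logical 3D gray-matter mask.
#' @param exclude_cols,exclude_rows widths of the excluded centre bands.
#' @return a `quadrant_map` (integer 3D array with codes LV=1, RV=2, LD=3,
#'   RD=4, excluded=5 and attribute `flagged_slices`).
#' @export
partition_gm_quadrants <- function(gm, exclude_cols = 3L, exclude_rows = 1L) {
  d <- dim(gm)
  stopifnot(length(d) == 3L)
  quad <- array(0L, d)
  flagged <- integer(0)
  for (z in seq_len(d[3])) {
    idx <- which(gm[, , z], arr.ind = TRUE)
    if (nrow(idx) == 0L) { flagged <- c(flagged, z); next }
    cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
    lab <- integer(nrow(idx))
    excl <- abs(idx[, 1] - cx) <= exclude_cols / 2 |
      abs(idx[, 2] - cy) <= exclude_rows / 2
    left <- idx[, 1] > cx          # +x is subject-left
    ventral <- idx[, 2] > cy       # +y is subject-anterior
    lab[!excl & left & ventral] <- QUAD_CODES[["LV"]]
    lab[!excl & !left & ventral] <- QUAD_CODES[["RV"]]
    lab[!excl & left & !ventral] <- QUAD_CODES[["LD"]]
    lab[!excl & !left & !ventral] <- QUAD_CODES[["RD"]]
    lab[excl] <- QUAD_CODES[["excluded"]]
    qz <- quad[, , z]
    qz[idx] <- lab
    quad[, , z] <- qz
    if (any(vapply(HORNS, function(h) sum(lab == QUAD_CODES[h]) == 0L,
                   TRUE)))
      flagged <- c(flagged, z)
  }
  quadrant_map(quad, flagged)
}

#' ROI mean time-series per slice and horn
#'
#' Unweighted mean over the labelled voxels of each quadrant, slice by
#' slice. Empty ROIs and flagged slices propagate as NA.
#'
#' @param v a [volume_series()].
#' @param q a `quadrant_map` on the same grid.
#' @return a 3D array `(slice, roi, volume)` with ROI names LV, RV, LD, RD.
#' @export
roi_timeseries <- function(v, q) {
  d <- dim(v$data)
  if (!all(dim(q)[1:3] == d[1:3]))
    stop("quadrant map grid does not match series", call. = FALSE)
  out <- array(NA_real_, c(d[3], 4L, d[4]),
               dimnames = list(NULL, HORNS, NULL))
  for (z in seq_len(d[3])) {
    qz <- as.vector(q[, , z])
    S <- slice_matrix(v, z)
    for (h in HORNS) {
      sel <- qz == QUAD_CODES[[h]]
      if (any(sel))
        out[z, h, ] <- colMeans(S[sel, , drop = FALSE])
    }
  }
  attr(out, "flagged_slices") <- attr(q, "flagged_slices")
  out
}

#' Within-slice horn-pair network correlations
#'
#' Pearson correlation between ROI-pair time-series within each slice for
#' the six networks (ventral-ventral, dorsal-dorsal, two ipsilateral and
#' two contralateral ventral-dorsal pairs), and the subject summary as the
#' plain mean over the central slices. Flagged or incomplete slices are
#' skipped and counted.
#'
#' @param roi_ts array from [roi_timeseries()].
#' @param config a [study_config()]; `central_slices` and `fisher_z` are
#'   used.
#' @return a list of class `network_correlations`: `per_slice` data frame
#'   (slice, network, r), `summary` named vector of six network means, and
#'   `n_slices_used` per network.
#' @export
network_correlations <- function(roi_ts, config = study_config()) {
  nz <- dim(roi_ts)[1]; nt <- dim(roi_ts)[3]
  if (nt < 3L) stop("need at least 3 time points", call. = FALSE)
  flagged <- attr(roi_ts, "flagged_slices")
  rows <- expand.grid(slice = seq_len(nz),
                      network = NETWORKS$network,
                      stringsAsFactors = FALSE)
  rows$r <- NA_real_
  for (k in seq_len(nrow(NETWORKS))) {
    a <- NETWORKS$a[k]; b <- NETWORKS$b[k]
    for (z in seq_len(nz)) {
      if (z %in% flagged) next
      x <- roi_ts[z, a, ]; y <- roi_ts[z, b, ]
      if (anyNA(x) || anyNA(y) || stats::sd(x) == 0 || stats::sd(y) == 0)
        next
      rows$r[rows$slice == z & rows$network == NETWORKS$network[k]] <-
        stats::cor(x, y)
    }
  }
  cz <- central_slice_range(nz, config$central_slices)
  summ <- numeric(nrow(NETWORKS)); used <- integer(nrow(NETWORKS))
  for (k in seq_len(nrow(NETWORKS))) {
    rv <- rows$r[rows$network == NETWORKS$network[k] & rows$slice %in% cz]
    rv <- rv[!is.na(rv)]
    used[k] <- length(rv)
    summ[k] <- if (!length(rv)) NA_real_
      else if (config$fisher_z) tanh(mean(atanh(pmin(pmax(rv, -1 + 1e-12),
                                                     1 - 1e-12))))
      else mean(rv)
  }
  names(summ) <- names(used) <- NETWORKS$network
  structure(list(per_slice = rows, summary = summ, n_slices_used = used,
                 central_slices = cz),
            class = "network_correlations")
}

#' @export
print.network_correlations <- function(x, ...) {
  cat("<network_correlations> central-slice summary:\n")
  print(round(x$summary, 3))
  invisible(x)
}

#' Seed-based correlation map
#'
#' Pearson correlation of every in-mask voxel with the seed voxel's
#' time-series, thresholded (positive tail by default); the unthresholded
#' signed map is retained.
#'
#' @param v a [volume_series()].
#' @param seed integer voxel index `c(x, y, z)`; must lie inside `mask`.
#' @param mask logical 3D array restricting the map.
#' @param r_thresh correlation threshold.
#' @param positive_only if `TRUE`, threshold only positive correlations.
#' @return an object of class `seed_map` with `r` (signed map, NA outside
#'   the mask), `suprathreshold` (logical 3D array) and the seed index.
#' @export
seed_correlation_map <- function(v, seed, mask, r_thresh = 0.4,
                                 positive_only = TRUE) {
  d <- dim(v$data)
  stopifnot(length(seed) == 3L)
  if (!all(dim(mask) == d[1:3]))
    stop("mask grid does not match series", call. = FALSE)
  if (!mask[seed[1], seed[2], seed[3]])
    stop("seed voxel is outside the mask", call. = FALSE)
  sts <- v$data[seed[1], seed[2], seed[3], ]
  if (stats::sd(sts) == 0) stop("seed time-series has zero variance",
                                call. = FALSE)
  nvox <- prod(d[1:3])
  X <- matrix(v$data, nvox, d[4])
  sel <- which(as.vector(mask))
  Xs <- X[sel, , drop = FALSE] - rowMeans(X[sel, , drop = FALSE])
  s0 <- sts - mean(sts)
  denom <- sqrt(rowSums(Xs^2)) * sqrt(sum(s0^2))
  rv <- as.vector(Xs %*% s0) / ifelse(denom > 0, denom, NA)
  rmap <- array(NA_real_, d[1:3])
  rmap[sel] <- rv
  supra <- array(FALSE, d[1:3])
  supra[sel] <- if (positive_only) !is.na(rv) & rv >= r_thresh
    else !is.na(rv) & abs(rv) >= r_thresh
  structure(list(r = rmap, suprathreshold = supra, seed = seed,
                 r_thresh = r_thresh, positive_only = positive_only),
            class = "seed_map")
}
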