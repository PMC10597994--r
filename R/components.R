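#' Threshold component z-maps
#'
#' Re-standardises each spatial component within the analysis mask and
#' binarises it at `z >= z_thresh`.
#'
#' @param result a `group_ica_result` from [group_spatial_ica()].
#' @param z_thresh threshold (default 4).
#' @return a list with `binary` and `signed`: 4D arrays
#'   `(x, y, z, component)` (NA outside the mask in `signed`).
#' @export
component_zmaps <- function(result, z_thresh = 4.0) {
  mask <- result$mask
  d <- dim(mask)
  k <- result$n_components
  sel <- which(as.vector(mask))
  signed <- array(NA_real_, c(d, k))
  binary <- array(FALSE, c(d, k))
  for (i in seq_len(k)) {
    zvals <- result$zmaps[i, ]
    zvals <- (zvals - mean(zvals)) / stats::sd(zvals)
    s3 <- array(NA_real_, d); s3[sel] <- zvals
    b3 <- array(FALSE, d); b3[sel] <- zvals >= z_thresh
    signed[, , , i] <- s3
    binary[, , , i] <- b3
  }
  list(binary = binary, signed = signed, z_thresh = z_thresh)
}

#' Dice spatial overlap of two binary maps
#'
#' `2 |A n B| / (|A| + |B|)`; calling it with two empty maps is an error.
#'
#' @param a,b logical arrays of identical shape.
#' @return overlap in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("maps differ in shape", call. = FALSE)
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0L) stop("both maps are empty", call. = FALSE)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Classify a thresholded component
#'
#' Labels a component as gray matter, white matter or noise from its
#' suprathreshold extent: GM when most suprathreshold voxels and the peak
#' z-score lie in gray matter; WM when confined to the cord but not
#' GM-dominant; noise when mostly outside the cord, or wider in-plane than
#' the cord while extending over a single slice. GM components receive a
#' ventral / dorsal / intermediate-central subtype from the quadrant of
#' the peak voxel, and a left / right / bilateral / midline side label.
#'
#' @param binary logical 3D suprathreshold map.
#' @param signed numeric 3D z-map (NA outside the analysis mask).
#' @param masks a [mask_set()] on the same (cropped) grid.
#' @param quadrants a `quadrant_map` on the same grid.
#' @param config a [study_config()]; occupancy/bilaterality thresholds.
#' @return a list of class `component_label`: `tissue`, `subtype`, `side`,
#'   `slice_extent`, `n_voxels`.
#' @export
classify_component <- function(binary, signed, masks, quadrants,
                               config = study_config()) {
  lab <- function(tissue, subtype = NA_character_, side = NA_character_,
                  extent = 0L, nv = 0L)
    structure(list(tissue = tissue, subtype = subtype, side = side,
                   slice_extent = extent, n_voxels = nv),
              class = "component_label")
  nv <- sum(binary)
  if (nv == 0L) return(lab("noise", extent = 0L, nv = 0L))
  idx <- which(binary, arr.ind = TRUE)
  zs <- sort(unique(idx[, 3]))
  extent <- length(zs)
  in_cord <- masks$cord[binary]
  in_gm <- masks$gm[binary]
  pk <- which(binary & !is.na(signed), arr.ind = TRUE)
  pkv <- signed[binary & !is.na(signed)]
  peak <- pk[which.max(pkv), ]
  # in-plane footprint vs cord width
  xr <- diff(range(idx[, 1])) + 1L
  yr <- diff(range(idx[, 2])) + 1L
  cidx <- which(masks$cord, arr.ind = TRUE)
  cord_w <- max(diff(range(cidx[, 1])) + 1L, diff(range(cidx[, 2])) + 1L)
  frac_cord <- mean(in_cord)
  if (frac_cord < 0.5 ||
      (extent == 1L && max(xr, yr) > config$noise_extent_frac * cord_w))
    return(lab("noise", extent = extent, nv = nv))
  gm_dominant <- mean(in_gm) >= config$gm_occupancy_frac
  peak_in_gm <- masks$gm[peak[1], peak[2], peak[3]]
  if (!(gm_dominant && peak_in_gm))
    return(lab("WM", extent = extent, nv = nv))
  # GM subtype from the quadrant of the peak voxel
  pq <- quadrants[peak[1], peak[2], peak[3]]
  subtype <- if (pq %in% QUAD_CODES[c("LV", "RV")]) "ventral"
    else if (pq %in% QUAD_CODES[c("LD", "RD")]) "dorsal"
    else "intermediate/central"
  # side from suprathreshold mass about the cord midline
  mid <- mean(cidx[, 1])
  n_left <- sum(idx[, 1] > mid + 0.5)
  n_right <- sum(idx[, 1] < mid - 0.5)
  side <- if (n_left >= config$bilateral_frac * nv &&
                n_right >= config$bilateral_frac * nv) "bilateral"
    else if (n_left > n_right) "left"
    else if (n_right > n_left) "right"
    else "midline"
  lab("GM", subtype, side, extent, nv)
}

#' @export
print.component_label <- function(x, ...) {
  cat(sprintf("<component_label> %s%s%s, %d voxels on %d slice(s)\n",
              x$tissue,
              if (!is.na(x$subtype)) paste0("/", x$subtype) else "",
              if (!is.na(x$side)) paste0("/", x$side) else "",
              x$n_voxels, x$slice_extent))
  invisible(x)
}

#' Match two sets of component maps by Dice overlap
#'
#' One-to-one assignment maximising total Dice (maximum-weight bipartite
#' matching); matched pairs with Dice below the floor are reported
#' unmatched.
#'
#' @param set_a,set_b lists of logical 3D maps (or 4D arrays with the
#'   component index last).
#' @param dice_floor minimum Dice for a pair to count as matched.
#' @return a data frame of class `match_table` with columns
#'   `component_a, component_b, dice, matched`.
#' @export
match_components <- function(set_a, set_b, dice_floor = 0.1) {
  as_list <- function(s) {
    if (is.array(s) && length(dim(s)) == 4L)
      lapply(seq_len(dim(s)[4]), function(i) s[, , , i])
    else s
  }
  set_a <- as_list(set_a); set_b <- as_list(set_b)
  na <- length(set_a); nb <- length(set_b)
  empty <- data.frame(component_a = integer(0), component_b = integer(0),
                      dice = numeric(0), matched = logical(0))
  class(empty) <- c("match_table", "data.frame")
  if (na == 0L || nb == 0L) return(empty)
  D <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (sum(set_a[[i]]) + sum(set_b[[j]]) > 0)
      D[i, j] <- dice(set_a[[i]], set_b[[j]])
  }
  # maximum-weight bipartite matching on positive-overlap edges
  edges <- which(D > 0, arr.ind = TRUE)
  tab <- empty
  if (nrow(edges)) {
    g <- igraph::make_bipartite_graph(c(rep(FALSE, na), rep(TRUE, nb)),
                                      edges = as.vector(t(cbind(edges[, 1],
                                                                na + edges[, 2]))))
    igraph::E(g)$weight <- D[edges]
    mm <- igraph::max_bipartite_match(g)$matching
    for (i in seq_len(na)) {
      j <- mm[i]
      if (!is.na(j)) {
        j <- as.integer(j) - na
        tab <- rbind(tab, data.frame(component_a = i, component_b = j,
                                     dice = D[i, j],
                                     matched = D[i, j] >= dice_floor))
      }
    }
  }
  class(tab) <- c("match_table", "data.frame")
  tab
}

#' Split-half group ICA reproducibility
#'
#' Runs the full registration, cropping, reduction, group ICA,
#' thresholding and classification chain independently on two sub-groups,
#' matches the GM-labelled components between groups by Dice and
#' summarises the overlap — the standard split-half check of ICA
#' stability.
#'
#' @param subjects list of denoised [volume_series()] objects.
#' @param masks_list list of per-subject [mask_set()]s (native space).
#' @param split integer vector of 1/2 group labels, one per subject,
#'   partitioning the cohort into two equal groups.
#' @param n_components ICA model order per group.
#' @param analysis_mask `"gm"` or `"cord"`: which target-subject mask
#'   defines the ICA voxel set.
#' @param config a [study_config()].
#' @param target index of the subject whose mean image and masks define
#'   the common space (default: first subject).
#' @param seed integer seed (per-group seeds derive from it).
#' @return a list of class `split_half_result` with `group1`, `group2`
#'   (each: `group_ica_result`, thresholded maps, labels), `matches`
#'   (a `match_table` over GM components), and `summary` (mean Dice over
#'   matched GM components and over matched ventral GM components).
#' @export
split_half_analysis <- function(subjects, masks_list, split,
                                n_components, analysis_mask = c("gm", "cord"),
                                config = study_config(), target = 1L,
                                seed = config$rng_seed) {
  analysis_mask <- match.arg(analysis_mask)
  n <- length(subjects)
  stopifnot(length(split) == n, all(split %in% c(1L, 2L)))
  if (sum(split == 1L) != sum(split == 2L))
    stop("split labels must form two equal groups", call. = FALSE)
  tgt_mean <- apply(subjects[[target]]$data, 1:3, mean)
  tgt_masks <- masks_list[[target]]
  run_group <- function(g, gseed) {
    idx <- which(split == g)
    reds <- vector("list", length(idx))
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      v <- subjects[[i]]
      if (i != target) {
        mov_mean <- apply(v$data, 1:3, mean)
        tf <- register_inplane(mov_mean, tgt_mean)
        v <- apply_inplane_transform(v, tf)
      }
      vc <- crop_to_enlargement(v, tgt_masks$cord, config$ica_crop_slices)
      rng <- attr(vc, "slice_range")
      amask <- tgt_masks[[analysis_mask]][, , rng, drop = FALSE]
      reds[[ii]] <- subject_pca_reduce(vc, amask,
                                       p1 = min(config$subject_pca_dims,
                                                dim(vc)[4] - 1L))
    }
    amask <- attr(reds[[1]], "mask")
    res <- group_spatial_ica(reds, amask, n_components, seed = gseed)
    zm <- component_zmaps(res, config$z_thresh)
    crop_rng <- attr(crop_to_enlargement(subjects[[target]],
                                         tgt_masks$cord,
                                         config$ica_crop_slices),
                     "slice_range")
    masks_c <- mask_set(tgt_masks$cord[, , crop_rng, drop = FALSE],
                        tgt_masks$gm[, , crop_rng, drop = FALSE],
                        tgt_masks$csf[, , crop_rng, drop = FALSE],
                        tgt_masks$notspine[, , crop_rng, drop = FALSE])
    quads <- partition_gm_quadrants(masks_c$gm)
    labels <- lapply(seq_len(n_components), function(i)
      classify_component(zm$binary[, , , i], zm$signed[, , , i],
                         masks_c, quads, config))
    list(ica = res, zmaps = zm, labels = labels, masks = masks_c)
  }
  g1 <- run_group(1L, seed)
  g2 <- run_group(2L, seed)
  gm_idx <- function(g) which(vapply(g$labels, function(l) l$tissue == "GM",
                                     TRUE))
  i1 <- gm_idx(g1); i2 <- gm_idx(g2)
  maps1 <- lapply(i1, function(i) g1$zmaps$binary[, , , i])
  maps2 <- lapply(i2, function(i) g2$zmaps$binary[, , , i])
  matches <- match_components(maps1, maps2, config$match_dice_floor)
  if (nrow(matches)) {
    matches$component_a <- i1[matches$component_a]
    matches$component_b <- i2[matches$component_b]
  }
  md <- matches$dice[matches$matched]
  ventral1 <- i1[vapply(g1$labels[i1],
                        function(l) identical(l$subtype, "ventral"), TRUE)]
  vd <- matches$dice[matches$matched & matches$component_a %in% ventral1]
  structure(list(group1 = g1, group2 = g2, matches = matches,
                 summary = c(mean_dice_gm = if (length(md)) mean(md) else NA_real_,
                             mean_dice_ventral = if (length(vd)) mean(vd) else NA_real_,
                             n_matched = length(md))),
            class = "split_half_result")
}

#' @export
print.split_half_result <- function(x, ...) {
  cat("<split_half_result>\n")
  print(round(x$summary, 3))
  invisible(x)
}
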