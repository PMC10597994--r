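# Quadrant label codes shared by the phantom ground truth and the
# data-driven partition: 0 none, 1..4 the four horns, 5 excluded bands.
QUAD_CODES <- c(LV = 1L, RV = 2L, LD = 3L, RD = 4L, excluded = 5L)
HORNS <- c("LV", "RV", "LD", "RD")

quadrant_map <- function(labels, flagged = integer(0)) {
  structure(labels, class = "quadrant_map", flagged_slices = flagged)
}

#' @export
print.quadrant_map <- function(x, ...) {
  counts <- vapply(HORNS, function(h) sum(x == QUAD_CODES[h]), 0L)
  cat("<quadrant_map>", paste(sprintf("%s: %d", HORNS, counts), collapse = ", "),
      sprintf("(excluded %d; %d flagged slices)\n", sum(x == QUAD_CODES["excluded"]),
              length(attr(x, "flagged_slices"))))
  invisible(x)
}

# per-slice geometric scale factors of the phantom cord
cord_scale_profile <- function(spec) {
  z0 <- seq_len(spec$nz) - 1
  pmax(1 - 0.02 * (z0 - (spec$enlargement_z - 1))^2, 0.86)
}

gm_taper_profile <- function(spec) {
  tp <- rep(1, spec$nz)
  k <- min(length(spec$gm_taper_caudal), spec$nz)
  tp[seq_len(k)] <- spec$gm_taper_caudal[seq_len(k)]
  tp
}

#' Build the phantom tissue masks and ground-truth horn labels
#'
#' Constructs, slice by slice, an elliptical cord containing four
#' gray-matter horn blobs (two ventral, two dorsal), a CSF annulus around
#' the cord, and a "not-spine" region covering everything outside the
#' spinal canal. Cord cross-sectional area peaks at the lumbar enlargement
#' slice and the horn blobs shrink on the most caudal slices, emulating the
#' disappearance of gray matter below the conus medullaris.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `masks` (a [mask_set()]), `quadrants`
#'   (ground-truth horn identities as a `quadrant_map`), `horn_counts`
#'   (slices x 4 voxel counts) and `cord_area_vox` (per-slice cord area).
#' @export
make_geometry <- function(spec) {
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz
  dx <- spec$voxel_mm[1]; dy <- spec$voxel_mm[2]
  cxv <- (nx + 1) / 2 + spec$geom_shift_vox[1]
  cyv <- (ny + 1) / 2 + spec$geom_shift_vox[2]
  X <- (matrix(seq_len(nx), nx, ny) - cxv) * dx
  Y <- (matrix(seq_len(ny), nx, ny, byrow = TRUE) - cyv) * dy
  sprof <- cord_scale_profile(spec)
  tprof <- gm_taper_profile(spec)
  g <- spec$geom_scale
  cord <- gm <- csf <- array(FALSE, c(nx, ny, nz))
  quad <- array(0L, c(nx, ny, nz))
  horn_counts <- matrix(0L, nz, 4, dimnames = list(NULL, HORNS))
  cord_area <- integer(nz)
  for (z in seq_len(nz)) {
    s <- sprof[z] * g
    a <- spec$cord_semi_mm[1] * s; b <- spec$cord_semi_mm[2] * s
    in_cord <- (X / a)^2 + (Y / b)^2 <= 1
    ao <- a + spec$csf_width_mm * g; bo <- b + spec$csf_width_mm * g
    in_canal <- (X / ao)^2 + (Y / bo)^2 <= 1
    slice_gm <- matrix(FALSE, nx, ny)
    for (h in HORNS) {
      ctr <- spec$horn_centers_mm[[h]] * s
      semi <- spec$horn_semi_mm[[h]] * s * tprof[z]
      in_horn <- ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 <= 1
      if (any(in_horn & !in_cord))
        stop("horn ", h, " overlaps the cord boundary on slice ", z,
             call. = FALSE)
      slice_gm <- slice_gm | in_horn
      qz <- quad[, , z]
      qz[in_horn] <- QUAD_CODES[[h]]
      quad[, , z] <- qz
      horn_counts[z, h] <- sum(in_horn)
    }
    cord[, , z] <- in_cord
    gm[, , z] <- slice_gm
    csf[, , z] <- in_canal & !in_cord
    cord_area[z] <- sum(in_cord)
  }
  notspine <- array(TRUE, c(nx, ny, nz))
  for (z in seq_len(nz)) {
    s <- sprof[z] * g
    ao <- spec$cord_semi_mm[1] * s + spec$csf_width_mm * g
    bo <- spec$cord_semi_mm[2] * s + spec$csf_width_mm * g
    notspine[, , z] <- (X / ao)^2 + (Y / bo)^2 > 1
  }
  list(masks = mask_set(cord, gm, csf, notspine),
       quadrants = quadrant_map(quad),
       horn_counts = horn_counts,
       cord_area_vox = cord_area)
}

# in-plane distance-to-cord-edge profile in mm (1 at boundary, ~0 deep
# inside), used to localise cardiac/CSF-pulsation amplitude at the
# cord/CSF interface
cord_edge_profile <- function(spec, z_scale) {
  nx <- spec$nx; ny <- spec$ny
  dx <- spec$voxel_mm[1]; dy <- spec$voxel_mm[2]
  cxv <- (nx + 1) / 2 + spec$geom_shift_vox[1]
  cyv <- (ny + 1) / 2 + spec$geom_shift_vox[2]
  X <- (matrix(seq_len(nx), nx, ny) - cxv) * dx
  Y <- (matrix(seq_len(ny), nx, ny, byrow = TRUE) - cyv) * dy
  a <- spec$cord_semi_mm[1] * z_scale; b <- spec$cord_semi_mm[2] * z_scale
  rho <- sqrt((X / a)^2 + (Y / b)^2)        # 1 on the cord boundary
  edge_mm <- (1 - pmin(rho, 1)) * min(a, b) # approx distance to edge
  exp(-edge_mm / 0.8)
}
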