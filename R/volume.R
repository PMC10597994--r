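#' Construct a 4D volume time-series
#'
#' The central data object of the package: a 4D array indexed `(x, y, z, t)`
#' with its grid spacing and volume acquisition time. `+x` is subject-left,
#' `+y` subject-anterior (ventral), and slice `z = 1` the most caudal slice.
#'
#' @param data 4D numeric array `(x, y, z, t)`; all values finite.
#' @param voxel_mm length-3 positive voxel size `(dx, dy, dz)` in mm.
#' @param tr_s volume acquisition time in seconds.
#' @param space_tag free-text provenance label, e.g. `"native"`.
#' @return an object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_mm, tr_s, space_tag = "native") {
  if (length(dim(data)) != 4L)
    stop("expected 4D data, got ", length(dim(data)), "D", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all four dimensions must be >= 1", call. = FALSE)
  nbad <- sum(!is.finite(data))
  if (nbad > 0L)
    stop("data contains ", nbad, " non-finite voxel values", call. = FALSE)
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
    stop("voxel_mm must be three positive sizes", call. = FALSE)
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("tr_s must be a single positive number", call. = FALSE)
  structure(list(data = data, voxel_mm = voxel_mm, tr_s = as.numeric(tr_s),
                 slice_order = "caudal-to-rostral", space_tag = space_tag),
            class = "volume_series")
}

#' @export
dim.volume_series <- function(x) dim(x$data)

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d voxels x %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel %.3g x %.3g x %.3g mm, TR %.3g s, space '%s'\n",
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3], x$tr_s, x$space_tag))
  invisible(x)
}

nifti_reference <- function(dims, voxel_mm, tr_s = 0) {
  nd <- length(dims)
  dimfield <- c(nd, dims, rep(1L, 7L - length(dims)))
  pd <- c(-1, voxel_mm, tr_s, 0, 0, 0)
  RNifti::niftiHeader(list(dim = dimfield, pixdim = pd))
}

#' Read and write 4D series as NIfTI-1
#'
#' Grid spacing and TR are taken from (written to) the header `pixdim`
#' field. Data are stored as float32, so a round-trip is exact to single
#' precision. Axis order is preserved: a voxel at index `(i, j, k, t)`
#' before writing is at the same index after reading.
#'
#' @param path a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param tr_s optional TR override, required when the file header has a
#'   zero time step.
#' @param v a [volume_series()].
#' @return `read_volume_series()` returns a `volume_series`;
#'   `write_volume_series()` returns `path` invisibly.
#' @export
read_volume_series <- function(path, tr_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected 4D image, got ", length(d), "D: ", path, call. = FALSE)
  # raw header: RNifti's image accessors normalise a zero TR away
  pd <- abs(RNifti::niftiHeader(path)$pixdim[2:5])
  hdr_tr <- pd[4]
  if (is.null(tr_s)) {
    if (!is.finite(hdr_tr) || hdr_tr <= 0)
      stop("header TR is zero or invalid in ", path,
           "; pass tr_s explicitly", call. = FALSE)
    tr_s <- hdr_tr
  }
  arr <- array(as.numeric(img), dim = d)
  nbad <- sum(!is.finite(arr))
  if (nbad > 0L)
    stop("image contains ", nbad, " non-finite voxel values: ", path,
         call. = FALSE)
  volume_series(arr, voxel_mm = pd[1:3], tr_s = tr_s)
}

#' @rdname read_volume_series
#' @export
write_volume_series <- function(v, path) {
  stopifnot(inherits(v, "volume_series"))
  ref <- nifti_reference(dim(v$data), v$voxel_mm, v$tr_s)
  img <- RNifti::asNifti(v$data, reference = ref, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write binary masks as NIfTI-1
#'
#' On reading, values are binarised at 0.5. When a reference series is
#' supplied the mask grid must match its spatial dimensions.
#'
#' @param path NIfTI-1 file.
#' @param reference optional [volume_series()] whose spatial grid the mask
#'   must match.
#' @param mask logical (or 0/1) 3D array.
#' @param voxel_mm voxel size written to the header.
#' @return `read_mask()` returns a logical 3D array; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { d <- d[1:3]; dim(img) <- d }
  if (length(d) != 3L)
    stop("expected a 3D mask, got ", length(d), "D: ", path, call. = FALSE)
  if (!is.null(reference)) {
    rd <- dim(reference$data)[1:3]
    if (!all(d == rd))
      stop(sprintf("mask grid %s does not match series grid %s",
                   paste(d, collapse = "x"), paste(rd, collapse = "x")),
           call. = FALSE)
  }
  array(as.numeric(img) > 0.5, dim = d)
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path, voxel_mm = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3L)
  ref <- nifti_reference(dim(mask), voxel_mm)
  img <- RNifti::asNifti(array(as.integer(mask != 0), dim = dim(mask)),
                         reference = ref, datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Bundle tissue masks on a common grid
#'
#' Holds the cord, gray matter, CSF and "not-spine" (everything outside the
#' spinal canal) masks used by the denoising and ROI stages, and checks
#' their containment relations: GM lies inside the cord, CSF is disjoint
#' from the cord, and not-spine is disjoint from the canal (cord + CSF).
#'
#' @param cord,gm,csf,notspine logical 3D arrays on the same grid.
#' @return an object of class `mask_set`.
#' @export
mask_set <- function(cord, gm, csf, notspine) {
  ms <- list(cord = cord != 0, gm = gm != 0, csf = csf != 0,
             notspine = notspine != 0)
  d <- dim(ms$cord)
  stopifnot(length(d) == 3L)
  for (nm in names(ms))
    if (!all(dim(ms[[nm]]) == d))
      stop("mask '", nm, "' is not on the common grid", call. = FALSE)
  if (any(ms$gm & !ms$cord)) stop("gm mask extends outside cord", call. = FALSE)
  if (any(ms$csf & ms$cord)) stop("csf mask intersects cord", call. = FALSE)
  if (any(ms$notspine & (ms$cord | ms$csf)))
    stop("notspine mask intersects the spinal canal", call. = FALSE)
  for (nm in names(ms))
    if (sum(ms[[nm]]) == 0L)
      stop("mask '", nm, "' is empty", call. = FALSE)
  structure(ms, class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat("<mask_set>",
      paste(sprintf("%s: %d vox", names(x), vapply(x, sum, 0L)),
            collapse = ", "), "\n")
  invisible(x)
}

slice_matrix <- function(v, z) {
  d <- dim(v$data)
  matrix(v$data[, , z, ], nrow = d[1] * d[2], ncol = d[4])
}
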