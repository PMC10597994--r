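# In-plane resampling primitives. shift_image() moves image content by
# (+tx, +ty) voxels using bilinear interpolation with edge clamping:
# out(x, y) = img(x - tx, y - ty).

shift_image <- function(img, tx, ty) {
  nx <- nrow(img); ny <- ncol(img)
  xs <- pmin(pmax(seq_len(nx) - tx, 1), nx)
  ys <- pmin(pmax(seq_len(ny) - ty, 1), ny)
  x0 <- pmin(floor(xs), nx - 1L); fx <- xs - x0
  y0 <- pmin(floor(ys), ny - 1L); fy <- ys - y0
  rows <- img[x0, , drop = FALSE] * (1 - fx) + img[x0 + 1L, , drop = FALSE] * fx
  rows[, y0, drop = FALSE] * rep(1 - fy, each = nx) +
    rows[, y0 + 1L, drop = FALSE] * rep(fy, each = nx)
}

# translation + isotropic scale about the grid centre:
# out(x) = img(c + (x - c - t) / s)
transform_image <- function(img, tx, ty, scale = 1) {
  nx <- nrow(img); ny <- ncol(img)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xs <- pmin(pmax(cx + (seq_len(nx) - cx - tx) / scale, 1), nx)
  ys <- pmin(pmax(cy + (seq_len(ny) - cy - ty) / scale, 1), ny)
  x0 <- pmin(floor(xs), nx - 1L); fx <- xs - x0
  y0 <- pmin(floor(ys), ny - 1L); fy <- ys - y0
  rows <- img[x0, , drop = FALSE] * (1 - fx) + img[x0 + 1L, , drop = FALSE] * fx
  rows[, y0, drop = FALSE] * rep(1 - fy, each = nx) +
    rows[, y0 + 1L, drop = FALSE] * rep(fy, each = nx)
}

# separable Gaussian blur with replicated edges (small fixed radius)
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  nx <- nrow(img); ny <- ncol(img)
  pad <- img[c(rep(1L, r), 1:nx, rep(nx, r)), c(rep(1L, r), 1:ny, rep(ny, r))]
  tmp <- matrix(0, nx, ny + 2L * r)
  for (j in seq_len(ny + 2L * r))
    tmp[, j] <- as.numeric(stats::filter(pad[, j], k, sides = 2))[(r + 1L):(r + nx)]
  out <- matrix(0, nx, ny)
  for (i in seq_len(nx))
    out[i, ] <- as.numeric(stats::filter(tmp[i, ], k, sides = 2))[(r + 1L):(r + ny)]
  out
}
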