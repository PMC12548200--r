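# Shared helpers for 3-D volumes. Volumes are plain numeric/logical arrays
# indexed (x, y, z), 1-based; the world coordinate of the centre of voxel
# (i, j, k) is ((i, j, k) - 0.5) * spacing, with the image origin at the
# corner of the first voxel. All physical quantities are in mm.

check_vol3 <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    abort(paste0("`", name, "` must be a 3-D array"))
  invisible(x)
}

check_same_dim <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    abort(paste0("shape mismatch: ", what, " must share the same grid"))
  invisible(NULL)
}

check_spacing <- function(spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be 3 positive voxel sizes in mm")
  as.numeric(spacing)
}

#' @noRd
voxel_centers_mm <- function(dim, spacing, axis) {
  (seq_len(dim[axis]) - 0.5) * spacing[axis]
}

# Coordinate grids as long vectors in array order (x fastest).
index_grid <- function(dm) {
  list(
    i = rep.int(seq_len(dm[1]), dm[2] * dm[3]),
    j = rep.int(rep(seq_len(dm[2]), each = dm[1]), dm[3]),
    k = rep(seq_len(dm[3]), each = dm[1] * dm[2])
  )
}

# Shift an array by `by` voxels along `axis`, padding with `fill`.
shift_array <- function(a, by, axis, fill = 0) {
  if (by == 0) return(a)
  dm <- dim(a)
  n <- dm[axis]
  if (abs(by) >= n) return(array(fill, dm))
  idx_src <- if (by > 0) seq_len(n - by) else seq(1 - by, n)
  idx_dst <- if (by > 0) seq(1 + by, n) else seq_len(n + by)
  out <- array(fill, dm)
  src <- dst <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  src[[axis]] <- idx_src
  dst[[axis]] <- idx_dst
  out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(a), src, list(drop = FALSE))))))
  out
}

gaussian_kernel_1d <- function(sigma, radius) {
  stopifnot(sigma > 0, radius >= 1)
  x <- seq(-radius, radius)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

#' Separable Gaussian smoothing of a 3-D volume
#'
#' Truncated, normalised Gaussian kernel applied along each axis in turn.
#' Near the array boundary the result is renormalised by the local kernel
#' mass so constant volumes stay constant all the way to the edge.
#'
#' @param vol 3-D numeric array.
#' @param sigma kernel standard deviation in voxels (scalar).
#' @param radius truncation radius in voxels.
#' @return smoothed array with the same dimensions.
#' @export
gaussian_smooth <- function(vol, sigma, radius = max(1L, ceiling(3 * sigma))) {
  check_vol3(vol)
  if (sigma <= 0) return(vol)
  w <- gaussian_kernel_1d(sigma, radius)
  offs <- seq(-radius, radius)
  out <- vol
  norm <- array(1, dim(vol))
  for (axis in 1:3) {
    acc <- array(0, dim(vol))
    accw <- array(0, dim(vol))
    for (m in seq_along(offs)) {
      acc <- acc + w[m] * shift_array(out, offs[m], axis)
      accw <- accw + w[m] * shift_array(norm, offs[m], axis)
    }
    out <- acc
    norm <- accw
  }
  out / norm
}

# Trilinear interpolation of `vol` at continuous 1-based voxel coordinates.
# Points outside the grid return `outside_value` and are flagged.
resample_trilinear <- function(vol, ix, iy, iz, outside_value = 0) {
  dm <- dim(vol)
  inside <- ix >= 1 & ix <= dm[1] & iy >= 1 & iy <= dm[2] & iz >= 1 & iz <= dm[3]
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  x0 <- pmin(pmax(x0, 1), dm[1] - 1)
  y0 <- pmin(pmax(y0, 1), dm[2] - 1)
  z0 <- pmin(pmax(z0, 1), dm[3] - 1)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  lin <- function(xi, yi, zi) vol[cbind(xi, yi, zi)]
  v000 <- lin(x0,     y0,     z0)
  v100 <- lin(x0 + 1, y0,     z0)
  v010 <- lin(x0,     y0 + 1, z0)
  v110 <- lin(x0 + 1, y0 + 1, z0)
  v001 <- lin(x0,     y0,     z0 + 1)
  v101 <- lin(x0 + 1, y0,     z0 + 1)
  v011 <- lin(x0,     y0 + 1, z0 + 1)
  v111 <- lin(x0 + 1, y0 + 1, z0 + 1)
  val <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) +
    v100 * fx       * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy       * (1 - fz) +
    v110 * fx       * fy       * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz +
    v101 * fx       * (1 - fy) * fz +
    v011 * (1 - fx) * fy       * fz +
    v111 * fx       * fy       * fz
  val[!inside] <- outside_value
  list(values = val, inside = inside)
}

# Partial derivative of each voxel of `vol` along `axis` in world units:
# central differences in the interior, one-sided at the two boundary slabs.
fd_gradient <- function(vol, axis, step) {
  fwd <- shift_array(vol, -1, axis)  # value at index + 1
  bwd <- shift_array(vol, +1, axis)  # value at index - 1
  g <- (fwd - bwd) / (2 * step)
  dm <- dim(vol)
  idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  lo <- hi <- idx
  lo[[axis]] <- 1L
  hi[[axis]] <- dm[axis]
  lo2 <- hi2 <- idx
  lo2[[axis]] <- 2L
  hi2[[axis]] <- dm[axis] - 1L
  g_lo <- (do.call(`[`, c(list(vol), lo2, list(drop = FALSE))) -
             do.call(`[`, c(list(vol), lo, list(drop = FALSE)))) / step
  g_hi <- (do.call(`[`, c(list(vol), hi, list(drop = FALSE))) -
             do.call(`[`, c(list(vol), hi2, list(drop = FALSE)))) / step
  g <- do.call(`[<-`, c(list(g), lo, list(g_lo)))
  g <- do.call(`[<-`, c(list(g), hi, list(g_hi)))
  g
}

#' Write / read a volume as NIfTI
#'
#' Thin wrappers around [RNifti::writeNifti()] and [RNifti::readNifti()] that
#' carry the voxel spacing.
#'
#' @param vol 3-D array (or 4-D for vector fields).
#' @param path file path, typically ending in `.nii.gz`.
#' @param spacing voxel size in mm (length 3).
#' @export
write_volume <- function(vol, path, spacing = c(1, 1, 1)) {
  spacing <- check_spacing(spacing)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(spacing, length.out = length(dim(vol)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  structure(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img))
}
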