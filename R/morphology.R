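# Binary 3-D morphology with spherical structuring elements, built on an
# exact squared Euclidean distance transform (see src/edt.cpp). A ball of
# radius r contains every voxel whose centre lies within distance r, so
#   dilate(A, r) = { x : dist(x, A)  <= r }
#   erode(A, r)  = { x : dist(x, A^c) > r }

#' Squared Euclidean distance transform
#'
#' Distance from each voxel centre to the nearest `TRUE` voxel of `mask`,
#' squared, in units set by `spacing`. Exact (Felzenszwalb–Huttenlocher
#' lower-envelope algorithm).
#'
#' @param mask logical 3-D array.
#' @param spacing per-axis sample spacing (default voxel units).
#' @return numeric array of squared distances (a large sentinel value where
#'   `mask` has no `TRUE` voxel at all).
#' @export
edt_squared <- function(mask, spacing = c(1, 1, 1)) {
  check_vol3(mask)
  spacing <- check_spacing(spacing)
  d <- .edt_sq_cpp(as.logical(mask), dim(mask), spacing)
  array(d, dim(mask))
}

#' Binary morphology with a spherical structuring element
#'
#' @param mask logical 3-D array.
#' @param radius ball radius in voxels.
#' @name morphology
NULL

#' @rdname morphology
#' @export
binary_dilate <- function(mask, radius) {
  edt_squared(mask) <= radius^2 + 1e-9
}

#' @rdname morphology
#' @export
binary_erode <- function(mask, radius) {
  mask & !(edt_squared(!mask) <= radius^2 + 1e-9)
}

#' @rdname morphology
#' @export
binary_open <- function(mask, radius) {
  binary_dilate(binary_erode(mask, radius), radius)
}

#' @rdname morphology
#' @export
binary_close <- function(mask, radius) {
  binary_erode(binary_dilate(mask, radius), radius)
}

#' Smooth and expand a lung mask for registration
#'
#' Morphological opening (removes speckle), closing (bridges fissures and
#' vessels) and dilation (margin for the deformable registration), all with
#' spherical elements. The default radii of 2, 15 and 10 voxels are the
#' values used with 1 mm isotropic scans; scale them down for coarser grids.
#'
#' @param mask logical (or 0/1) 3-D array; must contain at least one voxel.
#' @param open_radius,close_radius,dilate_radius ball radii in voxels.
#' @return logical array of the processed mask.
#' @export
prepare_mask <- function(mask, open_radius = 2, close_radius = 15,
                         dilate_radius = 10) {
  check_vol3(mask)
  mask <- mask > 0
  if (!any(mask)) abort("`mask` is empty")
  m <- binary_open(mask, open_radius)
  m <- binary_close(m, close_radius)
  binary_dilate(m, dilate_radius)
}
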