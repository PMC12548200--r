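# Perfused-blood-volume analysis: iodine images are restricted to the lung
# parenchyma (vessels excluded), clipped and normalised so the sum over a
# region of interest gives that region's fraction of the total perfused
# blood volume. Three ROIs per scan: the whole right lung and the left lung
# split axially into two equal-volume halves.

#' Vessel segmentation by threshold region growing
#'
#' 26-connected region growing from seed points over voxels above the
#' threshold; the resulting mask is excluded from the parenchyma.
#'
#' @param vol HU (or iodine) array.
#' @param seed_points matrix (n x 3) of seed world coordinates, mm.
#' @param threshold_hu voxels strictly above this value are growable.
#' @param spacing voxel size in mm.
#' @return logical mask of the grown region.
#' @export
segment_vessels <- function(vol, seed_points, threshold_hu,
                            spacing = c(1, 1, 1)) {
  check_vol3(vol)
  spacing <- check_spacing(spacing)
  seed_points <- matrix(seed_points, ncol = 3)
  dm <- dim(vol)
  vi <- floor(sweep(seed_points, 2, spacing, "/")) + 1
  if (any(vi < 1) || any(sweep(vi, 2, dm, ">")))
    abort("seed point outside the volume")
  growable <- vol > threshold_hu
  seeds <- array(FALSE, dm)
  seeds[vi] <- TRUE
  if (!any(seeds & growable))
    abort("no seed lies above the threshold: empty growth")
  region <- seeds & growable
  repeat {
    grown <- region
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      grown <- grown |
        shift_array(shift_array(shift_array(region, dx, 1, FALSE),
                                dy, 2, FALSE), dz, 3, FALSE)
    }
    grown <- grown & growable
    if (identical(grown, region)) break
    region <- grown
  }
  region
}

#' Tissue mass from a virtual non-contrast image
#'
#' Water-equivalent CT mass convention: density
#' `rho = 1 + HU/1000` g/ml, clipped to `[0, 1.1]`, times the voxel volume.
#'
#' @param vnc VNC HU array.
#' @param voxel_volume_ml voxel volume in ml.
#' @return array of voxel tissue masses in g.
#' @export
tissue_mass <- function(vnc, voxel_volume_ml) {
  check_vol3(vnc)
  rho <- 1 + vnc / 1000
  rho[rho < 0] <- 0
  rho[rho > 1.1] <- 1.1
  rho * voxel_volume_ml
}

#' Normalised perfused-blood-volume map
#'
#' Restricts the iodine image to the parenchyma minus vessels, clips
#' negative values, and divides by the sum so the map sums to exactly 1.
#'
#' @param iodine iodine-enhancement array (HU).
#' @param parenchyma logical parenchyma mask.
#' @param vessels optional logical vessel mask to exclude.
#' @param clip_negative clip negative iodine before normalising.
#' @return a `perfusion_map` list: `pp` (fractions summing to 1 over the
#'   mask), `mask`.
#' @export
perfusion_map <- function(iodine, parenchyma, vessels = NULL,
                          clip_negative = TRUE) {
  check_vol3(iodine)
  check_same_dim(iodine, parenchyma, "iodine and parenchyma mask")
  mask <- parenchyma > 0
  if (!is.null(vessels)) {
    check_same_dim(iodine, vessels, "iodine and vessel mask")
    mask <- mask & !(vessels > 0)
  }
  vals <- iodine
  vals[!mask] <- 0
  if (clip_negative) vals[vals < 0] <- 0
  s <- sum(vals)
  if (s <= 0) abort("degenerate input: iodine image is all zero inside the mask")
  structure(list(pp = vals / s, mask = mask), class = "perfusion_map")
}

#' Split the lungs into the three analysis ROIs
#'
#' Right lung as one ROI; the left lung split along the axial direction
#' into two equal-volume halves: the split slice index `k` is the first
#' slice at which the cumulative left-lung voxel count reaches half the
#' total. Slices before `k` are cranial, `k` onwards caudal (the tie slice
#' goes caudal).
#'
#' @param left,right logical lung masks (vessels already excluded if they
#'   should not count).
#' @param axis axial array dimension (3 for the standard orientation,
#'   index increasing caudally).
#' @return an `roi_set`: `labels` array with 1 = right, 2 = left cranial,
#'   3 = left caudal; `split_slice`; `axis`.
#' @export
split_rois <- function(left, right, axis = 3) {
  check_vol3(left)
  check_same_dim(left, right, "lung masks")
  if (!any(left)) abort("left lung mask is empty")
  counts <- apply(left, axis, sum)
  k <- which(cumsum(counts) >= sum(counts) / 2)[1]
  dm <- dim(left)
  slice_idx <- slice.index(left, axis)
  labels <- array(0L, dm)
  labels[right > 0] <- 1L
  labels[left > 0 & slice_idx < k] <- 2L
  labels[left > 0 & slice_idx >= k] <- 3L
  structure(list(labels = labels, split_slice = k, axis = axis,
                 roi_names = c("right", "left_cranial", "left_caudal")),
            class = "roi_set")
}

#' Regional DECT perfusion fractions
#'
#' Per ROI, the perfusion-map sum divided by the ROI tissue mass, then the
#' three values renormalised to sum 1. Mass normalisation at ROI level (a
#' ratio of sums) avoids dividing by near-zero voxel masses.
#'
#' @param pp a [perfusion_map()].
#' @param mass voxel tissue-mass array from [tissue_mass()].
#' @param rois an `roi_set` from [split_rois()].
#' @return tibble with columns `roi`, `value`, `method = "DECT"`.
#' @export
regional_perfusion <- function(pp, mass, rois) {
  if (!inherits(pp, "perfusion_map")) abort("`pp` must be a perfusion_map")
  check_same_dim(pp$pp, rois$labels, "perfusion map and ROI labels")
  vals <- vapply(1:3, function(l) {
    m <- rois$labels == l
    ms <- sum(mass[m])
    if (ms <= 0) abort("ROI with zero tissue mass")
    sum(pp$pp[m]) / ms
  }, numeric(1))
  tibble::tibble(roi = rois$roi_names, value = vals / sum(vals),
                 method = "DECT")
}

#' Iodine accumulation table from pre-contrast scans
#'
#' Mean VNC and iodine HU per aeration region for a series of pre-contrast
#' decompositions; the downstream trend test (repeated-measures
#' mixed-effects model) is left to standard tools.
#'
#' @param pre_contrast_decomps list of `decomposition_result`s, one per
#'   timepoint.
#' @param regions named list with logical masks `aerated`, `non_aerated`.
#' @param times_h acquisition times in hours, one per decomposition.
#' @return tibble with `2 * 2 * length(times_h)` rows: `time_h`, `region`,
#'   `image`, `mean_hu`.
#' @export
accumulation_table <- function(pre_contrast_decomps, regions, times_h) {
  if (length(pre_contrast_decomps) != length(times_h))
    abort("`times_h` must have one entry per decomposition")
  purrr::map2_dfr(pre_contrast_decomps, times_h, function(dec, t) {
    tidyr::expand_grid(region = c("aerated", "non_aerated"),
                       image = c("VNC", "iodine")) |>
      dplyr::mutate(
        time_h = t,
        mean_hu = purrr::map2_dbl(.data$region, .data$image, function(rg, im) {
          m <- regions[[rg]]
          vol <- if (im == "VNC") dec$vnc else dec$iodine
          mean(vol[m > 0])
        })
      ) |>
      dplyr::select("time_h", "region", "image", "mean_hu")
  })
}

#' Paired ventilation/perfusion profiles along an anatomical axis
#'
#' Sums the ventilation map and the perfusion map per slice along the
#' chosen axis inside the mask and normalises each profile to sum 1 (raw
#' normalised sums; no mass weighting).
#'
#' @param dv a `ventilation_map` (or dv array).
#' @param pp a `perfusion_map` (or pp array).
#' @param axis `"ventrodorsal"` (dimension 2) or `"caudocranial"`
#'   (dimension 3).
#' @param mask logical mask; defaults to the perfusion-map mask.
#' @param spacing voxel size in mm (for the position column).
#' @return tibble with columns `axis`, `slice`, `position_mm`, `dv`, `pp`.
#' @export
vq_profiles <- function(dv, pp, axis = c("ventrodorsal", "caudocranial"),
                        mask = NULL, spacing = c(1, 1, 1)) {
  axis <- match.arg(axis)
  dim_idx <- if (axis == "ventrodorsal") 2L else 3L
  dv_arr <- if (inherits(dv, "ventilation_map")) dv$dv else dv
  pp_arr <- if (inherits(pp, "perfusion_map")) pp$pp else pp
  if (is.null(mask)) {
    mask <- if (inherits(pp, "perfusion_map")) pp$mask else array(TRUE, dim(pp_arr))
  }
  check_same_dim(dv_arr, pp_arr, "dv and pp")
  spacing <- check_spacing(spacing)
  dvm <- dv_arr * mask
  ppm <- pp_arr * mask
  dv_prof <- apply(dvm, dim_idx, sum)
  pp_prof <- apply(ppm, dim_idx, sum)
  out <- tibble::tibble(
    axis = axis,
    slice = seq_along(dv_prof),
    position_mm = (seq_along(dv_prof) - 0.5) * spacing[dim_idx],
    dv = dv_prof / sum(dv_prof),
    pp = pp_prof / sum(pp_prof)
  )
  attr(out, "normalisation") <- "raw slice sums, each profile normalised to 1"
  out
}

#' Classify voxels into V/Q matching categories
#'
#' Both maps are normalised to sum 1 over the mask; the per-voxel ratio
#' `R = dv_norm / pp_norm` is thresholded: `R > upper` is dead-space-like
#' (ventilated but scarcely perfused), `R < lower` shunt-like (perfused but
#' scarcely ventilated), otherwise matched.
#'
#' @param dv a `ventilation_map` or dv array.
#' @param pp a `perfusion_map` or pp array.
#' @param mask logical mask; defaults to the perfusion-map mask.
#' @param ratio_bounds `c(lower, upper)` thresholds on R.
#' @return integer label array: 0 outside mask, 1 matched, 2
#'   dead-space-like, 3 shunt-like; quadrant-style counts in attribute
#'   `counts`.
#' @export
vq_classify <- function(dv, pp, mask = NULL, ratio_bounds = c(0.5, 2)) {
  dv_arr <- if (inherits(dv, "ventilation_map")) dv$dv else dv
  pp_arr <- if (inherits(pp, "perfusion_map")) pp$pp else pp
  if (is.null(mask)) {
    mask <- if (inherits(pp, "perfusion_map")) pp$mask else array(TRUE, dim(pp_arr))
  }
  check_same_dim(dv_arr, pp_arr, "dv and pp")
  lower <- ratio_bounds[1]
  upper <- ratio_bounds[2]
  if (!(lower < upper)) abort("`ratio_bounds` must satisfy lower < upper")
  dvn <- dv_arr / sum(dv_arr[mask])
  ppn <- pp_arr / sum(pp_arr[mask])
  lab <- array(0L, dim(dv_arr))
  inm <- which(mask)
  d <- dvn[inm]
  q <- ppn[inm]
  cls <- rep(1L, length(inm))                       # matched
  dead <- (q <= 0 & d > 0) | (q > 0 & d / q > upper)
  shunt <- q > 0 & d / q < lower
  cls[dead] <- 2L
  cls[shunt] <- 3L
  lab[inm] <- cls
  counts <- c(matched = sum(cls == 1L), dead_space = sum(cls == 2L),
              shunt = sum(cls == 3L))
  attr(lab, "counts") <- counts
  lab
}
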