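# Digital thorax phantom with known ventilation and perfusion ground truth.
#
# Geometry (voxel-centre convention, world mm = (index - 0.5) * spacing):
# two ellipsoidal lungs in a soft-tissue background, a central airway, and
# one bright vessel tube per lung. Axis 1 is left-right, axis 2
# ventro-dorsal (index increases dorsally), axis 3 cranio-caudal (index
# increases caudally). Gas fraction falls ventro-dorsally, as in a supine
# subject, and is apodised to zero at the pleural boundary so that every
# rendered image is smooth across the lung edge.
#
# Breathing is modelled as an axial (caudal) scaling of each ventilated lung
# about its apex by `expansion_factor`. The scaling is applied to every
# z-column that intersects the ventilated lung (its axial shadow), which
# makes the displacement piecewise linear in z and the Jacobian determinant
# exactly `expansion_factor` at every ventilated-lung voxel, including the
# apex/base voxels. Gas fraction is transported along the deformation
# (F_ei(T(x)) = F_ee(x)), so the per-voxel tidal gas-volume change at
# end-expiratory geometry is dv = (expansion_factor - 1) * F_ee.
#
# Under one-lung ventilation (OLV) only the left lung ventilates; the right
# lung keeps its end-expiratory geometry and `perfusion_shift` of total
# perfusion moves to the left lung (hypoxic vasoconstriction of the
# collapsed side). The right lung is sized to half the left lung volume so
# that the three analysis ROIs (right, left cranial, left caudal) are of
# comparable size, mimicking a partially collapsed right lung.

FLM_COLOR_GAINS <- c(blue = 100, blue_green = 125, yellow_green = 85,
                     scarlet = 110, red = 95)

#' Phantom configuration
#'
#' @param grid_shape voxel counts per axis (all >= 16).
#' @param voxel_size_mm voxel spacing in mm.
#' @param scenario `"TLV"` (two-lung ventilation) or `"OLV"` (left-sided
#'   one-lung ventilation: right lung neither ventilated nor aerated
#'   beyond its end-expiratory state).
#' @param perfusion_shift fraction of total perfusion assigned to the left
#'   lung under OLV (ignored under TLV, where the split is 0.5/0.5).
#' @param iodine_gain_hu_per_mgml HU enhancement in the high-energy spectrum
#'   per mg/ml iodine.
#' @param iodine_ratio spectral ratio of iodine attenuation, low over high
#'   energy (> 1).
#' @param iodine_mean_mgml mean iodine concentration over the parenchyma
#'   after contrast; only the product gain x concentration matters
#'   downstream because perfusion maps are sum-normalised.
#' @param noise_sd_hu additive Gaussian noise per DECT spectrum, HU.
#' @param n_microspheres number of microspheres per injection (desk-scale
#'   default 15000).
#' @param expansion_factor axial scale between end-expiration and
#'   end-inspiration (> 1).
#' @param weight_noise_sd relative Gaussian noise on cube weights.
#' @param fluorescence_noise_sdlog log-sd of multiplicative lognormal noise
#'   on cube fluorescence.
#' @param olv_iodine_bias multiplicative measurement bias on iodine in the
#'   non-ventilated right lung under OLV (1 = unbiased); models the
#'   decomposition error in dense atelectatic tissue.
#' @param vessel_iodine_mgml iodine concentration in the vessel tubes.
#' @param seed RNG seed consumed by [make_phantom()]; `NULL` leaves the
#'   caller's RNG stream untouched (used by the pipeline, which seeds once
#'   per run).
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64),
                           voxel_size_mm = c(3, 3, 3),
                           scenario = c("TLV", "OLV"),
                           perfusion_shift = 0.8,
                           iodine_gain_hu_per_mgml = 25,
                           iodine_ratio = 1.46,
                           iodine_mean_mgml = 2,
                           noise_sd_hu = 5,
                           n_microspheres = 15000,
                           expansion_factor = 1.25,
                           weight_noise_sd = 0.02,
                           fluorescence_noise_sdlog = 0.05,
                           olv_iodine_bias = 1,
                           vessel_iodine_mgml = 10,
                           seed = NULL) {
  scenario <- match.arg(scenario)
  grid_shape <- as.integer(grid_shape)
  voxel_size_mm <- check_spacing(voxel_size_mm)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    abort("`grid_shape` must be 3 voxel counts, all >= 16")
  if (!(perfusion_shift > 0 && perfusion_shift < 1))
    abort("`perfusion_shift` must be strictly between 0 and 1")
  if (iodine_ratio <= 1) abort("`iodine_ratio` must exceed 1")
  if (expansion_factor <= 1) abort("`expansion_factor` must exceed 1")
  if (n_microspheres < 1) abort("`n_microspheres` must be >= 1")
  if (noise_sd_hu < 0) abort("`noise_sd_hu` must be >= 0")
  cfg <- list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
              scenario = scenario, perfusion_shift = perfusion_shift,
              iodine_gain_hu_per_mgml = iodine_gain_hu_per_mgml,
              iodine_ratio = iodine_ratio, iodine_mean_mgml = iodine_mean_mgml,
              noise_sd_hu = noise_sd_hu, n_microspheres = n_microspheres,
              expansion_factor = expansion_factor,
              weight_noise_sd = weight_noise_sd,
              fluorescence_noise_sdlog = fluorescence_noise_sdlog,
              olv_iodine_bias = olv_iodine_bias,
              vessel_iodine_mgml = vessel_iodine_mgml, seed = seed)
  structure(cfg, class = "phantom_config")
}

# Lung geometry in continuous voxel units (voxel i covers [i-1, i]).
# Lungs are barrel-shaped generalised ellipsoids (exponent 6 along z):
# X^2 + Y^2 + Z^6 <= 1 in normalised coordinates. The flat axial profile
# keeps the 12 mm dissection cubes mostly full, as in a real lung that is
# large relative to the cutting grid. The right lung has half the left
# volume (collapsed under the right-sided pneumothorax of the study
# design), which also makes the three analysis ROIs comparable in size.
phantom_geometry <- function(cfg) {
  dm <- cfg$grid_shape
  left_semi <- c(0.19, 0.27, 0.335) * dm
  right_semi <- left_semi * RIGHT_LUNG_SCALE
  geo <- list(
    left = list(center = c(0.24, 0.50, 0.439) * dm, semi = left_semi),
    right = list(center = c(0.76, 0.50, 0.439) * dm, semi = right_semi)
  )
  for (side in names(geo)) {
    g <- geo[[side]]
    geo[[side]]$apex_z <- g$center[3] - g$semi[3]
    geo[[side]]$base_z <- g$center[3] + g$semi[3]
  }
  if (any(left_semi < 2))
    abort("grid too small to contain two lungs; increase `grid_shape`")
  worst_base <- geo$left$apex_z +
    (geo$left$base_z - geo$left$apex_z) * cfg$expansion_factor
  if (worst_base > dm[3] - 1 ||
      geo$left$center[1] + left_semi[1] >= geo$right$center[1] - right_semi[1])
    abort("grid too small to contain two lungs; increase `grid_shape`")
  geo$airway <- list(x = 0.5 * dm[1], y = 0.5 * dm[2],
                     radius = max(1.2, 0.023 * dm[1]),
                     z_lo = 0.06 * dm[3], z_hi = geo$left$center[3])
  geo
}

VENTRAL_GAS <- 0.72
DORSAL_GAS <- 0.47
TAPER_INNER <- 0.65
AXIAL_PERF_GRADIENT <- 0.2 # perfusion-per-mass rises 0.9 -> 1.1 apex->base
RIGHT_LUNG_SCALE <- 0.797  # right lung at about half the left volume

ventilated_sides <- function(scenario) {
  if (scenario == "TLV") c("left", "right") else "left"
}

# Evaluate phantom label and gas-fraction fields at (x, y, zq), all in
# continuous voxel units. Used for both respiratory phases: the
# end-inspiratory grid is sampled through the inverse axial scaling.
phantom_sample <- function(cfg, geo, x, y, zq) {
  dm <- cfg$grid_shape
  labels <- integer(length(x))
  fgas <- numeric(length(x))
  apod <- numeric(length(x))
  in_side <- list()
  taper <- function(rho) {
    t <- numeric(length(rho))
    t[rho <= TAPER_INNER] <- 1
    ramp <- rho > TAPER_INNER & rho <= 1
    t[ramp] <- 0.5 * (1 + cos(pi * (rho[ramp] - TAPER_INNER) / (1 - TAPER_INNER)))
    t
  }
  for (side in c("left", "right")) {
    g <- geo[[side]]
    rho <- sqrt(((x - g$center[1]) / g$semi[1])^2 +
                  ((y - g$center[2]) / g$semi[2])^2 +
                  ((zq - g$center[3]) / g$semi[3])^6)
    inlung <- rho <= 1
    in_side[[side]] <- inlung
    labels[inlung] <- if (side == "left") 1L else 2L
    tp <- taper(rho)
    apod[inlung] <- tp[inlung]
    yfrac <- pmin(pmax((y - (g$center[2] - g$semi[2])) / (2 * g$semi[2]), 0), 1)
    fg <- (VENTRAL_GAS - (VENTRAL_GAS - DORSAL_GAS) * yfrac) * tp
    fgas[inlung] <- fg[inlung]
    # vessel tube along z on the lung axis
    vr <- max(1.0, 0.018 * dm[1])
    vz_lo <- g$center[3] - 0.6 * g$semi[3]
    vz_hi <- g$center[3] + 0.6 * g$semi[3]
    vessel <- ((x - g$center[1])^2 + (y - g$center[2])^2 <= vr^2) &
      zq >= vz_lo & zq <= vz_hi & inlung
    labels[vessel] <- 4L
    fgas[vessel] <- 0
  }
  aw <- geo$airway
  airway <- ((x - aw$x)^2 + (y - aw$y)^2 <= aw$radius^2) &
    zq >= aw$z_lo & zq <= aw$z_hi & labels == 0L
  labels[airway] <- 3L
  fgas[airway] <- 1
  list(labels = labels, fgas = fgas, apod = apod,
       in_left = in_side$left, in_right = in_side$right)
}

#' Build the phantom ground truth
#'
#' Constructs every field the downstream modules estimate: labels, gas
#' fractions at both respiratory phases, iodine concentration, the
#' perfusion-fraction field (sums to exactly 1 over the parenchyma), the
#' analytic end-expiration to end-inspiration displacement field and its
#' Jacobian determinant, and the per-voxel tidal gas-volume change.
#'
#' @param config a [phantom_config()].
#' @return a `phantom_truth` list; volumes are arrays on the configured
#'   grid. `labels` codes: 0 background, 1 left lung, 2 right lung,
#'   3 airway, 4 vessel. `gas_fraction_ei` and `labels_ei` live on the
#'   end-inspiratory grid (same array shape, warped content).
#' @export
make_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) abort("`config` must be a phantom_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  dm <- config$grid_shape
  sp <- config$voxel_size_mm
  geo <- phantom_geometry(config)
  s <- config$expansion_factor
  vent_sides <- ventilated_sides(config$scenario)

  ig <- index_grid(dm)
  xc <- ig$i - 0.5
  yc <- ig$j - 0.5
  zc <- ig$k - 0.5

  ee <- phantom_sample(config, geo, xc, yc, zc)
  labels <- array(ee$labels, dm)
  f_ee <- array(ee$fgas, dm)

  # axial shadows of the ventilated lungs (disjoint in x by construction)
  shadow <- list()
  for (side in c("left", "right")) {
    g <- geo[[side]]
    rxy <- ((xc - g$center[1]) / g$semi[1])^2 + ((yc - g$center[2]) / g$semi[2])^2
    shadow[[side]] <- array(rxy <= 1, dm)
  }

  uz_vox <- numeric(length(xc))  # displacement in voxel units along z
  zprime <- zc                   # inverse-warped z used to render inspiration
  jac <- array(1, dm)
  for (side in vent_sides) {
    g <- geo[[side]]
    sh <- as.vector(shadow[[side]])
    uz_vox[sh] <- (s - 1) * (zc[sh] - g$apex_z)
    zprime[sh] <- g$apex_z + (zc[sh] - g$apex_z) / s
    jac[array(sh, dm)] <- s
  }
  displacement <- array(0, c(dm, 3L))
  displacement[, , , 3] <- array(uz_vox * sp[3], dm)

  ei <- phantom_sample(config, geo, xc, yc, zprime)
  labels_ei <- array(ei$labels, dm)
  f_ei <- array(ei$fgas, dm)

  parenchyma <- labels == 1L | labels == 2L
  ventilated <- parenchyma &
    array(Reduce(`|`, lapply(vent_sides, function(sd) as.vector(shadow[[sd]])),
                 accumulate = FALSE), dm)
  dv_true <- array(0, dm)
  dv_true[ventilated] <- (s - 1) * f_ee[ventilated]

  # perfusion: proportional to tissue density, apodised at the pleural rim
  # like the gas fraction (the dense apodisation rim is not hyperperfused),
  # with a mild apex->base rise in flow per unit mass; per-lung totals are
  # fixed by the scenario
  apod <- array(ee$apod, dm)
  tissue <- (1 - f_ee) * apod * parenchyma
  shares <- if (config$scenario == "TLV") c(left = 0.5, right = 0.5)
  else c(left = config$perfusion_shift, right = 1 - config$perfusion_shift)
  perf <- array(0, dm)
  for (side in c("left", "right")) {
    g <- geo[[side]]
    zfrac <- pmin(pmax((zc - g$apex_z) / (2 * g$semi[3]), 0), 1)
    w <- (1 - AXIAL_PERF_GRADIENT / 2) + AXIAL_PERF_GRADIENT * zfrac
    side_mask <- labels == (if (side == "left") 1L else 2L)
    raw <- tissue * array(w, dm) * side_mask
    tot <- sum(raw)
    if (tot <= 0) abort("degenerate phantom: lung without tissue")
    perf <- perf + shares[[side]] * raw / tot
  }

  iodine <- array(0, dm)
  iodine[parenchyma] <- config$iodine_mean_mgml *
    perf[parenchyma] / mean(perf[parenchyma])

  structure(list(
    config = config, spacing = sp, geometry = geo,
    labels = labels, labels_ei = labels_ei,
    gas_fraction_ee = f_ee, gas_fraction_ei = f_ei,
    iodine_concentration = iodine, perfusion_fraction = perf,
    displacement_field = displacement, jacobian = jac,
    dv_true = dv_true, parenchyma = parenchyma,
    ventilated = ventilated,
    lung_left = array(ee$in_left, dm), lung_right = array(ee$in_right, dm),
    vessel = labels == 4L
  ), class = "phantom_truth")
}

phantom_vnc_true <- function(truth) {
  hu <- array(40, dim(truth$labels))          # soft tissue
  lung <- truth$labels == 1L | truth$labels == 2L
  hu[lung] <- -1000 * truth$gas_fraction_ee[lung]
  hu[truth$labels == 3L] <- -1000             # airway
  hu[truth$labels == 4L] <- 50                # blood without iodine
  hu
}

#' Render a dual-energy CT scan of the phantom
#'
#' Forward model of the two-material decomposition: with iodine enhancement
#' `E = gain * concentration` (high-energy HU), the rendered pair is
#' `HU_high = VNC + E` and `HU_low = VNC + ratio * E`, plus independent
#' Gaussian noise per spectrum. The scan is acquired at mean lung volume,
#' approximated by the end-expiratory grid (gas fraction is preserved along
#' the phantom deformation, so the mean-volume gas fraction equals the
#' end-expiratory one at corresponding points).
#'
#' @param truth a `phantom_truth`.
#' @param config phantom configuration (defaults to the one in `truth`).
#' @param contrast render with (`TRUE`) or without (`FALSE`, pre-contrast
#'   scan) the iodine bolus.
#' @param background_iodine_hu persistent parenchymal iodine enhancement in
#'   high-energy HU, for accumulation experiments.
#' @return a `dect_scan` list with `hu_low`, `hu_high`, `spacing`.
#' @export
render_dect <- function(truth, config = truth$config, contrast = TRUE,
                        background_iodine_hu = 0) {
  vnc <- phantom_vnc_true(truth)
  dm <- dim(vnc)
  g <- config$iodine_gain_hu_per_mgml
  enh <- array(0, dm)
  if (contrast) {
    conc <- truth$iodine_concentration
    if (config$scenario == "OLV" && config$olv_iodine_bias != 1) {
      conc <- conc * ifelse(truth$lung_right, config$olv_iodine_bias, 1)
    }
    enh <- g * conc
    enh[truth$vessel] <- g * config$vessel_iodine_mgml
  }
  enh[truth$parenchyma] <- enh[truth$parenchyma] + background_iodine_hu
  hu_high <- vnc + enh
  hu_low <- vnc + config$iodine_ratio * enh
  if (config$noise_sd_hu > 0) {
    hu_low <- hu_low + array(rnorm(length(vnc), 0, config$noise_sd_hu), dm)
    hu_high <- hu_high + array(rnorm(length(vnc), 0, config$noise_sd_hu), dm)
  }
  dect_scan(hu_low, hu_high, spacing = truth$spacing)
}

#' Render a static (single-energy) CT scan of the phantom
#'
#' `HU = -1000 * gas fraction` inside the lung, soft tissue outside; the
#' end-inspiratory phase is rendered in the warped geometry.
#'
#' @param truth a `phantom_truth`.
#' @param phase `"ee"` (end-expiration) or `"ei"` (end-inspiration).
#' @return HU array with a `spacing` attribute.
#' @export
render_static_ct <- function(truth, phase = c("ee", "ei")) {
  phase <- match.arg(phase)
  labels <- if (phase == "ee") truth$labels else truth$labels_ei
  fgas <- if (phase == "ee") truth$gas_fraction_ee else truth$gas_fraction_ei
  hu <- array(40, dim(labels))
  lung <- labels == 1L | labels == 2L
  hu[lung] <- -1000 * fgas[lung]
  hu[labels == 3L] <- -1000
  hu[labels == 4L] <- 50
  attr(hu, "spacing") <- truth$spacing
  attr(hu, "phase") <- phase
  hu
}

# Cube index (0-based, per axis) of each voxel for an axis-aligned cube grid
# of `cube_mm` anchored at the image origin.
voxel_cube_index <- function(dm, spacing, cube_mm = 12) {
  ig <- index_grid(dm)
  cx <- floor(((ig$i - 0.5) * spacing[1]) / cube_mm)
  cy <- floor(((ig$j - 0.5) * spacing[2]) / cube_mm)
  cz <- floor(((ig$k - 0.5) * spacing[3]) / cube_mm)
  nx <- ceiling(dm[1] * spacing[1] / cube_mm)
  ny <- ceiling(dm[2] * spacing[2] / cube_mm)
  list(id = cx + nx * (cy + ny * cz), cx = cx, cy = cy, cz = cz)
}

#' Simulate a fluorescence-labelled microsphere measurement
#'
#' Draws `n_microspheres` deposition voxels from a multinomial with the
#' phantom's perfusion-fraction field, aggregates the counts into
#' axis-aligned 12 mm cubes (the postmortem dissection grid), and reports
#' per-cube weight and fluorescence with configurable noise. A cube counts
#' as lung when at least half of its voxels are parenchyma.
#'
#' @param truth a `phantom_truth`.
#' @param config phantom configuration (defaults to the one in `truth`).
#' @param color microsphere color label; its fixed fluorescence gain per
#'   sphere comes from an internal table and colors differ only by this
#'   scalar.
#' @param cube_mm cube edge length in mm.
#' @return tibble with columns `cube_x_mm`, `cube_y_mm`, `cube_z_mm`,
#'   `weight_mg`, `color`, `fluorescence_au`, `is_lung`, `n_spheres`, one
#'   row per cube containing any parenchyma.
#' @export
simulate_microspheres <- function(truth, config = truth$config,
                                  color = "blue", cube_mm = 12) {
  if (config$n_microspheres < 1) abort("`n_microspheres` must be >= 1")
  if (!color %in% names(FLM_COLOR_GAINS))
    abort(paste0("unknown microsphere color `", color, "`"))
  dm <- dim(truth$perfusion_fraction)
  sp <- truth$spacing
  par_idx <- which(truth$parenchyma)
  p <- truth$perfusion_fraction[par_idx]
  counts_par <- as.vector(rmultinom(1, config$n_microspheres, p))

  cubes <- voxel_cube_index(dm, sp, cube_mm)
  vox_ml <- prod(sp) / 1000
  tissue_mg <- (1 - truth$gas_fraction_ee) * vox_ml * 1000
  tissue_mg[!truth$parenchyma] <- 0

  id_all <- cubes$id
  df <- tibble::tibble(
    id = id_all,
    cx = cubes$cx, cy = cubes$cy, cz = cubes$cz,
    parench = as.vector(truth$parenchyma),
    mass = as.vector(tissue_mg)
  )
  df$count <- 0
  df$count[par_idx] <- counts_par
  agg <- df |>
    dplyr::group_by(.data$id, .data$cx, .data$cy, .data$cz) |>
    dplyr::summarise(
      n_vox = dplyr::n(),
      n_par = sum(.data$parench),
      weight_mg = sum(.data$mass),
      n_spheres = sum(.data$count),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_par > 0)

  gain <- FLM_COLOR_GAINS[[color]]
  n <- nrow(agg)
  fluo <- agg$n_spheres * gain
  if (config$fluorescence_noise_sdlog > 0)
    fluo <- fluo * exp(rnorm(n, 0, config$fluorescence_noise_sdlog))
  wt <- agg$weight_mg
  if (config$weight_noise_sd > 0)
    wt <- pmax(wt * (1 + rnorm(n, 0, config$weight_noise_sd)), 1e-6)

  tibble::tibble(
    cube_x_mm = (agg$cx + 0.5) * cube_mm,
    cube_y_mm = (agg$cy + 0.5) * cube_mm,
    cube_z_mm = (agg$cz + 0.5) * cube_mm,
    weight_mg = wt,
    color = color,
    fluorescence_au = fluo,
    is_lung = agg$n_par >= 0.5 * agg$n_vox,
    n_spheres = agg$n_spheres
  )
}

#' Ground-truth regional perfusion fractions of the phantom
#'
#' Reference values for the regional estimators. At `level = "voxel"` the
#' truth is aggregated directly from the perfusion-fraction field; with
#' `mass_normalised = TRUE` the per-ROI sums are divided by the ROI tissue
#' mass and renormalised, matching the DECT analysis chain. At
#' `level = "cube"` the truth mimics the microsphere estimator: expected
#' per-cube flow divided by cube mass, cubes assigned to ROIs by centre,
#' summed and renormalised.
#'
#' @param truth a `phantom_truth`.
#' @param rois an `roi_set` from [split_rois()].
#' @param level `"voxel"` or `"cube"`.
#' @param mass_normalised divide by tissue mass before renormalising
#'   (voxel level only; the cube level is always mass-normalised, as the
#'   microsphere assay is).
#' @param cube_mm cube edge length for `level = "cube"`.
#' @return tibble with columns `roi`, `value`.
#' @export
phantom_regional_truth <- function(truth, rois, level = c("voxel", "cube"),
                                   mass_normalised = TRUE, cube_mm = 12) {
  level <- match.arg(level)
  dm <- dim(truth$perfusion_fraction)
  sp <- truth$spacing
  roi_names <- c("right", "left_cranial", "left_caudal")
  if (level == "voxel") {
    vals <- vapply(1:3, function(l) {
      m <- rois$labels == l
      s <- sum(truth$perfusion_fraction[m])
      if (mass_normalised) {
        mass <- sum((1 - truth$gas_fraction_ee[m]))
        s <- s / mass
      }
      s
    }, numeric(1))
  } else {
    cubes <- voxel_cube_index(dm, sp, cube_mm)
    df <- tibble::tibble(
      id = cubes$id, cx = cubes$cx, cy = cubes$cy, cz = cubes$cz,
      parench = as.vector(truth$parenchyma),
      p = as.vector(truth$perfusion_fraction),
      mass = as.vector((1 - truth$gas_fraction_ee) * truth$parenchyma)
    )
    agg <- df |>
      dplyr::group_by(.data$id, .data$cx, .data$cy, .data$cz) |>
      dplyr::summarise(n_vox = dplyr::n(), n_par = sum(.data$parench),
                       p = sum(.data$p), mass = sum(.data$mass),
                       .groups = "drop") |>
      dplyr::filter(.data$n_par >= 0.5 * .data$n_vox, .data$mass > 0)
    ctr <- cbind((agg$cx + 0.5) * cube_mm, (agg$cy + 0.5) * cube_mm,
                 (agg$cz + 0.5) * cube_mm)
    vi <- floor(sweep(ctr, 2, sp, "/")) + 1
    ok <- vi[, 1] >= 1 & vi[, 1] <= dm[1] & vi[, 2] >= 1 & vi[, 2] <= dm[2] &
      vi[, 3] >= 1 & vi[, 3] <= dm[3]
    lab <- rep(0L, nrow(agg))
    lab[ok] <- rois$labels[vi[ok, , drop = FALSE]]
    vals <- vapply(1:3, function(l) sum((agg$p / agg$mass)[lab == l]),
                   numeric(1))
  }
  tibble::tibble(roi = roi_names, value = vals / sum(vals))
}

#' Write the phantom truth and rendered scans to a directory
#'
#' NIfTI volumes for the truth fields, both static phases and the DECT pair,
#' plus the microsphere table as CSV.
#'
#' @param truth a `phantom_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- truth$spacing
  write_volume(truth$labels + 0, file.path(dir, "labels.nii.gz"), sp)
  write_volume(truth$gas_fraction_ee, file.path(dir, "gas_fraction_ee.nii.gz"), sp)
  write_volume(truth$gas_fraction_ei, file.path(dir, "gas_fraction_ei.nii.gz"), sp)
  write_volume(truth$iodine_concentration, file.path(dir, "iodine_mgml.nii.gz"), sp)
  write_volume(truth$perfusion_fraction, file.path(dir, "perfusion_fraction.nii.gz"), sp)
  write_volume(truth$jacobian, file.path(dir, "jacobian.nii.gz"), sp)
  write_volume(truth$displacement_field, file.path(dir, "displacement_mm.nii.gz"), sp)
  scan <- render_dect(truth)
  write_volume(scan$hu_low, file.path(dir, "dect_low.nii.gz"), sp)
  write_volume(scan$hu_high, file.path(dir, "dect_high.nii.gz"), sp)
  write_volume(render_static_ct(truth, "ee"), file.path(dir, "static_ee.nii.gz"), sp)
  write_volume(render_static_ct(truth, "ei"), file.path(dir, "static_ei.nii.gz"), sp)
  readr::write_csv(simulate_microspheres(truth), file.path(dir, "microspheres.csv"))
  invisible(dir)
}
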