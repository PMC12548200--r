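# Regional ventilation from paired static CT scans. The tidal gas-volume
# change per voxel, evaluated at end-expiratory geometry, is
#   dv = F_gas,ei@ee * |J| - F_gas,ee
# where F_gas,ei@ee is the end-inspiratory gas fraction resampled through
# the end-expiration -> end-inspiration displacement field and |J| the
# field's Jacobian determinant (local volume-change factor).

#' Gas fraction from a CT volume
#'
#' `F_gas = HU / -1000` (air -1000 HU is pure gas, water 0 HU gas-free),
#' clipped to `[0, 1]`.
#'
#' @param hu HU array.
#' @return array of gas fractions.
#' @export
gas_fraction <- function(hu) {
  check_vol3(hu)
  if (any(!is.finite(hu))) abort("HU volume must be finite")
  f <- hu / -1000
  f[f < 0] <- 0
  f[f > 1] <- 1
  attributes(f) <- list(dim = dim(hu))
  f
}

#' Gaussian denoising of a gas-fraction volume
#'
#' A 3x3x3-support Gaussian kernel: sigma 0.75 voxels truncated at radius 1
#' by default, both configurable.
#'
#' @param f gas-fraction array.
#' @param sigma kernel sd in voxels.
#' @param radius truncation radius in voxels.
#' @export
denoise_gas_fraction <- function(f, sigma = 0.75, radius = 1) {
  gaussian_smooth(f, sigma, radius)
}

#' Registration engines
#'
#' [register_volumes()] takes a pluggable engine. `reg_engine_truth()` wraps
#' a known displacement field and returns it bit-exactly (ground-truth
#' passthrough, the reference engine for testing everything downstream of
#' registration). `reg_engine_demons()` is a small multi-resolution
#' demons-style deformable registrar for demonstrations: intensity-driven
#' updates regularised by Gaussian smoothing of the update (fluid) and of
#' the accumulated field (diffusion).
#'
#' @param field displacement array `dim x 3`, mm, on the fixed grid.
#' @param iterations iterations per resolution level, finest first; the
#'   length sets the number of levels (each level halves the grid).
#' @param sigma_fluid,sigma_diffusion regularisation sds in voxels.
#' @name reg_engine
#' @export
reg_engine_truth <- function(field) {
  structure(list(kind = "truth", field = field), class = "vq_reg_engine")
}

#' @rdname reg_engine
#' @export
reg_engine_demons <- function(iterations = c(40, 30, 30), sigma_fluid = 2.5,
                              sigma_diffusion = 0.4) {
  structure(list(kind = "demons", iterations = iterations,
                 sigma_fluid = sigma_fluid, sigma_diffusion = sigma_diffusion),
            class = "vq_reg_engine")
}

#' Deformable registration of two volumes
#'
#' Returns a displacement field `u` on the fixed grid, in mm, such that the
#' moving image resampled at `x + u(x)` aligns with the fixed image.
#'
#' @param fixed,moving 3-D arrays on comparable grids (e.g. gas fractions).
#' @param engine a registration engine, see [reg_engine_truth()].
#' @param spacing voxel size in mm.
#' @return displacement array of dimension `c(dim(fixed), 3)`, mm.
#' @export
register_volumes <- function(fixed, moving, engine = reg_engine_demons(),
                             spacing = c(1, 1, 1)) {
  check_vol3(fixed)
  check_vol3(moving)
  spacing <- check_spacing(spacing)
  if (any(!is.finite(fixed)) || any(!is.finite(moving)))
    abort("registration inputs must be finite")
  if (!inherits(engine, "vq_reg_engine")) abort("`engine` must be a registration engine")
  if (engine$kind == "truth") {
    fld <- engine$field
    if (!identical(dim(fld)[1:3], dim(fixed)))
      abort("ground-truth field grid does not match the fixed image")
    return(fld)
  }
  tryCatch(
    demons_register(fixed, moving, engine, spacing),
    error = function(e) abort(paste0("registration engine failed: ",
                                     conditionMessage(e)))
  )
}

downsample2 <- function(vol) {
  dm <- dim(vol)
  vol <- gaussian_smooth(vol, 0.85, 2)
  vol[seq(1, dm[1], 2), seq(1, dm[2], 2), seq(1, dm[3], 2), drop = FALSE]
}

upsample2_to <- function(vol, dm_out) {
  dm <- dim(vol)
  ig <- index_grid(dm_out)
  # coarse voxel i covers fine voxels 2i-1, 2i
  res <- resample_trilinear(vol, (ig$i + 0.5) / 2, (ig$j + 0.5) / 2,
                            (ig$k + 0.5) / 2)
  array(res$values, dm_out)
}

warp_image <- function(moving, u_vox) {
  dm <- dim(moving)
  ig <- index_grid(dm)
  res <- resample_trilinear(moving,
                            ig$i + as.vector(u_vox[, , , 1]),
                            ig$j + as.vector(u_vox[, , , 2]),
                            ig$k + as.vector(u_vox[, , , 3]))
  array(res$values, dm)
}

smooth_field <- function(u, sigma) {
  if (sigma <= 0) return(u)
  for (a in 1:3) u[, , , a] <- gaussian_smooth(u[, , , a], sigma)
  u
}

# Multi-resolution demons. Internally works in voxel units on each level.
demons_register <- function(fixed, moving, engine, spacing) {
  n_levels <- length(engine$iterations)
  pyr_f <- list(fixed)
  pyr_m <- list(moving)
  if (n_levels > 1) {
    for (l in 2:n_levels) {
      pyr_f[[l]] <- downsample2(pyr_f[[l - 1]])
      pyr_m[[l]] <- downsample2(pyr_m[[l - 1]])
    }
  }
  u <- NULL
  for (l in n_levels:1) {
    f <- pyr_f[[l]]
    m <- pyr_m[[l]]
    dm <- dim(f)
    if (is.null(u)) {
      u <- array(0, c(dm, 3L))
    } else {
      u_new <- array(0, c(dm, 3L))
      for (a in 1:3) u_new[, , , a] <- 2 * upsample2_to(u[, , , a], dm)
      u <- u_new
    }
    for (it in seq_len(engine$iterations[l])) {
      w <- warp_image(m, u)
      diff <- w - f
      gx <- fd_gradient(w, 1, 1)
      gy <- fd_gradient(w, 2, 1)
      gz <- fd_gradient(w, 3, 1)
      denom <- gx^2 + gy^2 + gz^2 + diff^2
      scale <- ifelse(denom > 1e-9, -diff / denom, 0)
      upd <- array(0, c(dm, 3L))
      upd[, , , 1] <- scale * gx
      upd[, , , 2] <- scale * gy
      upd[, , , 3] <- scale * gz
      # cap the update at one voxel for stability
      mag <- sqrt(upd[, , , 1]^2 + upd[, , , 2]^2 + upd[, , , 3]^2)
      cap <- ifelse(mag > 1, 1 / mag, 1)
      for (a in 1:3) upd[, , , a] <- upd[, , , a] * cap
      upd <- smooth_field(upd, engine$sigma_fluid)
      u <- smooth_field(u + upd, engine$sigma_diffusion)
    }
  }
  for (a in 1:3) u[, , , a] <- u[, , , a] * spacing[a]
  u
}

#' Jacobian determinant of a displacement field
#'
#' Determinant of the Jacobian of the mapping `x -> x + u(x)` in world
#' units: central finite differences in the interior, one-sided at the
#' volume boundary.
#'
#' @param field displacement array `dim x 3`, mm, on the fixed grid.
#' @param spacing voxel size in mm.
#' @return array of `|J|` values.
#' @export
jacobian_determinant <- function(field, spacing = c(1, 1, 1)) {
  if (length(dim(field)) != 4L || dim(field)[4] != 3L)
    abort("`field` must be a dim x 3 displacement array")
  spacing <- check_spacing(spacing)
  J <- vector("list", 9)
  for (a in 1:3) {
    for (b in 1:3) {
      J[[(a - 1) * 3 + b]] <- fd_gradient(field[, , , a], b, spacing[b]) +
        (a == b)
    }
  }
  j11 <- J[[1]]; j12 <- J[[2]]; j13 <- J[[3]]
  j21 <- J[[4]]; j22 <- J[[5]]; j23 <- J[[6]]
  j31 <- J[[7]]; j32 <- J[[8]]; j33 <- J[[9]]
  j11 * (j22 * j33 - j23 * j32) -
    j12 * (j21 * j33 - j23 * j31) +
    j13 * (j21 * j32 - j22 * j31)
}

#' Tidal gas-volume change map
#'
#' Resamples the end-inspiratory gas fraction through the displacement
#' field (trilinear), multiplies by the Jacobian determinant and subtracts
#' the end-expiratory gas fraction:
#' `dv = F_gas,ei@ee * |J| - F_gas,ee`, evaluated at end-expiratory
#' geometry and zeroed outside the mask. Voxels whose mapped position falls
#' outside the moving image take gas fraction 0 and are flagged.
#'
#' @param f_ee end-expiratory gas-fraction array (fixed grid).
#' @param f_ei end-inspiratory gas-fraction array (moving grid, same
#'   spacing).
#' @param field displacement array `dim x 3` in mm mapping ee -> ei.
#' @param mask logical lung mask on the fixed grid.
#' @param spacing voxel size in mm.
#' @param jacobian optional precomputed `|J|`; computed from `field` when
#'   `NULL`.
#' @return a `ventilation_map` list: `dv`, `mask`, `outside` (flagged
#'   voxels), `f_ei_at_ee`, `jacobian`, `spacing`.
#' @export
tidal_volume_change <- function(f_ee, f_ei, field, mask, spacing = c(1, 1, 1),
                                jacobian = NULL) {
  check_vol3(f_ee)
  check_vol3(f_ei)
  check_same_dim(f_ee, mask, "gas fraction and mask")
  if (!identical(dim(field)[1:3], dim(f_ee)))
    abort("grid mismatch between `field` and `f_ee`")
  spacing <- check_spacing(spacing)
  if (is.null(jacobian)) jacobian <- jacobian_determinant(field, spacing)
  dm <- dim(f_ee)
  ig <- index_grid(dm)
  res <- resample_trilinear(
    f_ei,
    ig$i + as.vector(field[, , , 1]) / spacing[1],
    ig$j + as.vector(field[, , , 2]) / spacing[2],
    ig$k + as.vector(field[, , , 3]) / spacing[3]
  )
  f_ei_at_ee <- array(res$values, dm)
  outside <- array(!res$inside, dm) & mask
  dv <- f_ei_at_ee * jacobian - f_ee
  dv[!mask] <- 0
  structure(list(dv = dv, mask = mask, outside = outside,
                 f_ei_at_ee = f_ei_at_ee, jacobian = jacobian,
                 spacing = spacing),
            class = "ventilation_map")
}
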