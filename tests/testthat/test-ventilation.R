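test_that("gas fraction maps HU linearly with clipping", {
  hu <- array(c(-1000, 0, -500, -1200, 100, -250), c(1, 2, 3))
  f <- gas_fraction(hu)
  expect_equal(as.vector(f), c(1, 0, 0.5, 1, 0, 0.25))
})

test_that("gaussian denoising preserves constants, mass and interior ramps", {
  dm <- c(16, 16, 16)
  expect_equal(denoise_gas_fraction(array(0.4, dm)), array(0.4, dm))
  delta <- array(0, dm)
  delta[8, 8, 8] <- 1
  sm <- denoise_gas_fraction(delta)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_lt(max(sm), 1)
  ig <- vqpipe:::index_grid(dm)
  ramp <- array(0.01 * ig$i + 0.02 * ig$j - 0.005 * ig$k, dm)
  smr <- denoise_gas_fraction(ramp)
  interior <- array(FALSE, dm)
  interior[3:14, 3:14, 3:14] <- TRUE
  expect_equal(smr[interior], ramp[interior], tolerance = 1e-12)
})

test_that("jacobian determinant handles identity, translation and affine stretch", {
  dm <- c(12, 12, 12)
  zero <- array(0, c(dm, 3))
  expect_equal(jacobian_determinant(zero), array(1, dm))
  shift <- zero
  shift[, , , 1] <- 2.5
  shift[, , , 3] <- -1
  expect_equal(jacobian_determinant(shift), array(1, dm))
  # u = 0.25 z in z: |J| = 1.25 everywhere (linear field, exact differences)
  ig <- vqpipe:::index_grid(dm)
  stretch <- zero
  stretch[, , , 3] <- array(0.25 * (ig$k - 0.5) * 2, dm)
  j <- jacobian_determinant(stretch, spacing = c(2, 2, 2))
  expect_lt(max(abs(j - 1.25)), 1e-6)
})

test_that("jacobian of a random smooth affine field matches its analytic determinant", {
  set.seed(21)
  dm <- c(10, 10, 10)
  A <- matrix(rnorm(9, 0, 0.05), 3, 3)
  ig <- vqpipe:::index_grid(dm)
  pos <- cbind(ig$i, ig$j, ig$k)
  u <- pos %*% t(A)
  field <- array(0, c(dm, 3))
  for (a in 1:3) field[, , , a] <- array(u[, a], dm)
  j <- jacobian_determinant(field)
  expect_lt(max(abs(j - det(diag(3) + A))), 1e-6)
})

test_that("the ground-truth registration engine is a bit-exact passthrough", {
  tr <- nf_phantom("TLV")
  fld <- register_volumes(tr$gas_fraction_ee, tr$gas_fraction_ei,
                          reg_engine_truth(tr$displacement_field), tr$spacing)
  expect_identical(fld, tr$displacement_field)
  expect_error(register_volumes(array(0, c(4, 4, 4)), array(0, c(4, 4, 4)),
                                reg_engine_truth(tr$displacement_field)),
               "does not match")
})

test_that("the demons demo registrar recovers identity and a known translation", {
  dm <- c(32, 32, 32)
  ig <- vqpipe:::index_grid(dm)
  blob <- function(cx) {
    array(exp(-(((ig$i - cx) / 8)^2 + ((ig$j - 16) / 8)^2 +
                  ((ig$k - 16) / 8)^2)), dm)
  }
  fixed <- blob(16)
  fld0 <- register_volumes(fixed, fixed,
                           reg_engine_demons(iterations = c(10, 10)))
  mag0 <- sqrt(fld0[, , , 1]^2 + fld0[, , , 2]^2 + fld0[, , , 3]^2)
  expect_lt(mean(mag0), 0.1)

  moving <- blob(13)  # alignment requires u_x = -3 voxels
  fld <- register_volumes(fixed, moving, reg_engine_demons())
  interior <- fixed > 0.3
  expect_equal(mean(fld[, , , 1][interior]), -3, tolerance = 0.1)
  expect_lt(mean(abs(fld[, , , 2][interior])), 0.3)
  warped <- vqpipe:::warp_image(moving, fld)
  expect_lt(mean(abs(warped - fixed)[interior]),
            0.05 * mean(abs(moving - fixed)[interior]))
})

test_that("tidal volume change reproduces scalar arithmetic on uniform fields", {
  dm <- c(8, 8, 8)
  mask <- array(TRUE, dm)
  f_ee <- array(0.5, dm)
  zero_field <- array(0, c(dm, 3))
  vm0 <- tidal_volume_change(f_ee, f_ee, zero_field, mask)
  expect_equal(vm0$dv, array(0, dm))
  # uniform 0.6 resampled through identity, |J| forced to 1.25
  vm <- tidal_volume_change(f_ee, array(0.6, dm), zero_field, mask,
                            jacobian = array(1.25, dm))
  expect_equal(vm$dv, array(0.6 * 1.25 - 0.5, dm))
})

test_that("ventilation maps recover the phantom truth and conserve gas volume", {
  tr <- nf_phantom("TLV")
  f_ee <- gas_fraction(render_static_ct(tr, "ee"))
  f_ei <- gas_fraction(render_static_ct(tr, "ei"))
  lung <- tr$parenchyma
  vm <- tidal_volume_change(f_ee, f_ei, tr$displacement_field, lung,
                            tr$spacing, jacobian = tr$jacobian)
  err <- vm$dv - tr$dv_true
  expect_lt(sqrt(mean(err[lung]^2)), 0.01)

  vvox <- prod(tr$spacing)
  tidal_est <- sum(vm$dv[lung]) * vvox
  tidal_true <- sum(tr$dv_true[lung]) * vvox
  expect_equal(tidal_est / tidal_true, 1, tolerance = 0.03)

  # transported gas volume equals the end-inspiratory gas volume
  gas_mapped <- sum((vm$f_ei_at_ee * vm$jacobian)[lung]) * vvox
  lung_ei <- tr$labels_ei %in% 1:2
  gas_ei <- sum(f_ei[lung_ei]) * vvox
  expect_equal(gas_mapped / gas_ei, 1, tolerance = 0.03)
  expect_true(all(vm$dv[!lung] == 0))
})
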