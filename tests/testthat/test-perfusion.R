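test_that("region growing segments exactly the bright tube", {
  tr <- nf_phantom("TLV")
  scan <- render_dect(tr)
  # vessel voxels render at 300 HU in the high-energy image, lung below -100
  seed_idx <- which(tr$vessel, arr.ind = TRUE)[1, ]
  seed_mm <- matrix((seed_idx - 0.5) * tr$spacing, 1)
  grown <- segment_vessels(scan$hu_high, seed_mm, -200, tr$spacing)
  expect_identical(which(grown), which(tr$vessel & tr$lung_left))

  expect_error(segment_vessels(scan$hu_high, seed_mm, 1e6, tr$spacing),
               "empty growth")
  expect_error(segment_vessels(scan$hu_high, matrix(c(-5, 0, 0), 1), -200,
                               tr$spacing), "outside")
})

test_that("tissue mass follows the water-equivalent density convention", {
  vnc <- array(c(-700, -1000, 0, 200), c(4, 1, 1))
  m <- tissue_mass(vnc, 0.027)
  expect_equal(as.vector(m), c(0.3, 0, 1, 1.1) * 0.027)
})

test_that("perfusion maps are normalised, scale-invariant and exclude vessels", {
  dm <- c(6, 6, 6)
  mask <- array(TRUE, dm)
  uniform <- perfusion_map(array(7, dm), mask)
  expect_equal(uniform$pp, array(1 / 216, dm))
  doubled <- perfusion_map(array(14, dm), mask)
  expect_equal(doubled$pp, uniform$pp)
  expect_error(perfusion_map(array(0, dm), mask), "degenerate")

  tr <- nf_phantom("TLV")
  dec <- decompose(render_dect(tr),
                   decomposition_config(iodine_ratio = tr$config$iodine_ratio))
  pp <- perfusion_map(dec$iodine, tr$parenchyma, tr$vessel)
  expect_equal(sum(pp$pp), 1, tolerance = 1e-9)
  expect_true(all(pp$pp[tr$vessel] == 0))
  rois <- nf_rois(tr)
  for (l in 1:3) {
    expect_equal(sum(pp$pp[rois$labels == l]),
                 sum(tr$perfusion_fraction[rois$labels == l]),
                 tolerance = 1e-3)
  }
})

test_that("the axial split makes equal-volume left halves", {
  # ten identical slices split 5/5
  dm <- c(4, 4, 10)
  left <- array(TRUE, dm)
  right <- array(FALSE, dm)
  rs <- split_rois(left, right)
  expect_equal(rs$split_slice, 5)
  expect_equal(sum(rs$labels == 2L), 4 * 4 * 4)
  expect_equal(sum(rs$labels == 3L), 4 * 4 * 6)

  # cumulative-count rule on uneven slices (1,1,1,1,6)
  left2 <- array(FALSE, c(2, 3, 5))
  left2[1, 1, 1:4] <- TRUE
  left2[, , 5] <- TRUE
  counts <- apply(left2, 3, sum)
  expect_equal(counts, c(1, 1, 1, 1, 6))
  rs2 <- split_rois(left2, array(FALSE, c(2, 3, 5)))
  expect_equal(rs2$split_slice, 5)
  expect_equal(sum(rs2$labels == 2L), 4)
  expect_equal(sum(rs2$labels == 3L), 6)

  # the right ROI is untouched by the split
  tr <- nf_phantom("TLV")
  rs3 <- nf_rois(tr)
  expect_identical(rs3$labels == 1L, tr$lung_right)
  expect_error(split_rois(array(FALSE, dm), right), "empty")
})

test_that("regional perfusion applies ROI-level mass normalisation", {
  dm <- c(6, 6, 6)
  labels <- array(rep(1:3, each = 72), dm)
  rois <- structure(list(labels = labels, split_slice = 3, axis = 3,
                         roi_names = c("right", "left_cranial", "left_caudal")),
                    class = "roi_set")
  pp_arr <- array(0, dm)
  pp_arr[labels == 1L] <- 0.5 / 72
  pp_arr[labels == 2L] <- 0.25 / 72
  pp_arr[labels == 3L] <- 0.25 / 72
  pp <- structure(list(pp = pp_arr, mask = array(TRUE, dm)),
                  class = "perfusion_map")
  # equal masses: mass cancels
  out <- regional_perfusion(pp, array(1, dm), rois)
  expect_equal(out$value, c(0.5, 0.25, 0.25))
  # masses (2, 1, 1): raw ratios become equal, renormalised to thirds
  mass <- array(1, dm)
  mass[labels == 1L] <- 2
  out2 <- regional_perfusion(pp, mass, rois)
  expect_equal(out2$value, rep(1 / 3, 3))
  expect_error(regional_perfusion(pp, array(0, dm), rois), "zero tissue mass")
})

test_that("end-to-end regional recovery matches the generator truth", {
  tr <- nf_phantom("TLV")
  res <- analyse_timepoint(tr, decomposition_config(
    iodine_ratio = tr$config$iodine_ratio))
  truth <- phantom_regional_truth(tr, res$rois, "voxel",
                                  mass_normalised = TRUE)
  dect <- dplyr::filter(res$regional, method == "DECT")
  expect_lt(max(abs(dect$value - truth$value)), 1e-2)
  expect_equal(sum(dect$value), 1, tolerance = 1e-9)
})

test_that("accumulation tables carry per-region mean HU over time", {
  tr <- nf_phantom("OLV")
  cfg <- tr$config
  dcfg <- decomposition_config(iodine_ratio = cfg$iodine_ratio,
                               clip_negative_iodine = FALSE)
  decs <- list(
    decompose(render_dect(tr, contrast = FALSE), dcfg),
    decompose(render_dect(tr, contrast = FALSE, background_iodine_hu = 10), dcfg)
  )
  regions <- list(aerated = tr$lung_left & tr$parenchyma,
                  non_aerated = tr$lung_right & tr$parenchyma)
  tab <- accumulation_table(decs, regions, times_h = c(0, 1))
  expect_equal(nrow(tab), 2 * 2 * 2)
  first_iod <- dplyr::filter(tab, time_h == 0, image == "iodine")
  expect_equal(first_iod$mean_hu, c(0, 0), tolerance = 1e-12)
  later_iod <- dplyr::filter(tab, time_h == 1, image == "iodine")
  expect_equal(later_iod$mean_hu, c(10, 10), tolerance = 1e-6)
  expect_error(accumulation_table(decs, regions, times_h = 0), "one entry")
})

test_that("V/Q profiles are normalised and ventrally ventilation-dominant", {
  tr <- nf_phantom("TLV")
  res <- analyse_timepoint(tr, decomposition_config(
    iodine_ratio = tr$config$iodine_ratio))
  vm <- tidal_volume_change(tr$gas_fraction_ee, tr$gas_fraction_ei,
                            tr$displacement_field, tr$parenchyma, tr$spacing,
                            jacobian = tr$jacobian)
  prof <- vq_profiles(vm, res$perfusion, "ventrodorsal", spacing = tr$spacing)
  expect_equal(sum(prof$dv), 1, tolerance = 1e-9)
  expect_equal(sum(prof$pp), 1, tolerance = 1e-9)
  # gravity-independent (ventral) half: relative ventilation exceeds perfusion
  ventral <- prof$slice <= dim(tr$labels)[2] / 2
  expect_gt(sum(prof$dv[ventral]), sum(prof$pp[ventral]))
  sel <- ventral & prof$dv > 0.005
  expect_true(all(prof$dv[sel] >= prof$pp[sel]))
  # proportional inputs give identical profiles
  prof2 <- vq_profiles(res$perfusion$pp * 3, res$perfusion$pp,
                       "caudocranial", mask = res$perfusion$mask)
  expect_equal(prof2$dv, prof2$pp)
})

test_that("V/Q classification is exhaustive, disjoint and matches a direct scan", {
  set.seed(14)
  dm <- c(16, 16, 16)
  mask <- array(TRUE, dm)
  dv <- array(abs(rnorm(prod(dm))), dm)
  pp <- array(abs(rnorm(prod(dm))), dm)
  pp[1, 1, 1] <- 0  # limiting case: ventilated but unperfused
  lab <- vq_classify(dv, pp, mask, ratio_bounds = c(0.5, 2))
  expect_true(all(lab %in% 1:3))
  # direct per-voxel oracle
  dvn <- dv / sum(dv)
  ppn <- pp / sum(pp)
  expected <- integer(prod(dm))
  for (i in seq_along(expected)) {
    expected[i] <- if (ppn[i] <= 0 && dvn[i] > 0) 2L
    else if (dvn[i] / ppn[i] > 2) 2L
    else if (dvn[i] / ppn[i] < 0.5) 3L
    else 1L
  }
  expect_equal(as.vector(lab), expected)
  counts <- attr(lab, "counts")
  expect_equal(sum(counts), prod(dm))
  # equal normalised maps are fully matched
  lab2 <- vq_classify(dv, dv, mask)
  expect_true(all(lab2 == 1L))
})
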