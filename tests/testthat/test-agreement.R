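pairs_from <- function(flm, dect, roi = "right", animal = "a1",
                       condition = "OLV") {
  tibble::tibble(animal = animal, timepoint = seq_along(flm),
                 condition = condition, roi = roi, pp_flm = flm,
                 pp_dect = dect)
}

test_that("regression matches the closed-form normal equations", {
  p <- pairs_from(c(0, 0.3, 0.7), c(0, 0.3, 0.7))
  r <- regress_methods(p)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$adj_r2, 1)

  p2 <- pairs_from(c(0, 0.5, 1), c(0.1, 0.5, 0.9))
  r2 <- regress_methods(p2)
  expect_equal(r2$slope, 0.8, tolerance = 1e-12)
  expect_equal(r2$intercept, 0.1, tolerance = 1e-12)

  set.seed(9)
  for (i in 1:5) {
    x <- runif(12)
    y <- 0.8 * x + rnorm(12, 0, 0.1)
    fit <- regress_methods(pairs_from(x, y))
    oracle <- oracle_ols(x, y)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$adj_r2, oracle$adj_r2, tolerance = 1e-10)
    expect_equal(fit$p_value, oracle$p_value, tolerance = 1e-10)
  }

  const <- regress_methods(pairs_from(c(0, 0.5, 1), c(0.4, 0.4, 0.4)))
  expect_equal(const$slope, 0)
  expect_equal(const$adj_r2, 0)
  expect_error(regress_methods(pairs_from(c(0.5, 0.5, 0.5), c(0, 0.5, 1))),
               "zero variance")
  expect_error(regress_methods(pairs_from(c(0, 1), c(0, 1))), "at least 3")
})

test_that("Bland-Altman bias and limits use the sample standard deviation", {
  same <- pairs_from(c(0.2, 0.5, 0.3), c(0.2, 0.5, 0.3))
  b <- bland_altman(same)
  expect_equal(c(b$bias, b$loa_low, b$loa_high), c(0, 0, 0))

  d <- c(0.02, -0.02, 0.04, -0.04)
  p <- pairs_from(rep(0.3, 4), 0.3 + d)
  b2 <- bland_altman(p)
  expect_equal(b2$bias, 0)
  expect_equal(b2$loa_high, 1.96 * sqrt(0.004 / 3), tolerance = 1e-12)
  expect_equal(b2$loa_high, 0.0716, tolerance = 1e-3)
  expect_equal(b2$loa_low, -b2$loa_high)

  shifted <- p
  shifted$pp_dect <- shifted$pp_dect + 0.1
  b3 <- bland_altman(shifted)
  expect_equal(b3$bias, b2$bias + 0.1)
  expect_equal(b3$loa_high - b3$loa_low, b2$loa_high - b2$loa_low)
  expect_error(bland_altman(p[1, ]), "at least 2")
})

test_that("concordance counts direction quadrants of consecutive changes", {
  up <- pairs_from(c(0.1, 0.2, 0.3, 0.4), c(0.2, 0.3, 0.4, 0.5))
  expect_equal(concordance(perfusion_changes(up))$concordance_pct, 100)

  ch <- tibble::tibble(d_flm = c(1, 2, -1, 1), d_dect = c(1, 0.5, -2, -1))
  k <- concordance(ch)
  expect_equal(k$concordance_pct, 75)
  expect_equal(c(k$q1, k$q2, k$q3, k$q4), c(2L, 0L, 1L, 1L))
  expect_equal(k$concordance_ratio, 3)

  flipped <- ch
  flipped$d_dect <- -flipped$d_dect
  expect_equal(concordance(flipped)$concordance_pct, 100 - 75)

  ties <- tibble::tibble(d_flm = c(0, 1), d_dect = c(1, 1))
  kt <- concordance(ties)
  expect_equal(kt$n_excluded, 1L)
  expect_equal(kt$concordance_pct, 100)
  expect_warning(concordance(tibble::tibble(d_flm = 0, d_dect = 0)),
                 "undefined")
})

test_that("changes are ordered by timepoint within animal and ROI", {
  p <- dplyr::bind_rows(
    pairs_from(c(0.5, 0.3, 0.4), c(0.5, 0.2, 0.45), roi = "right"),
    pairs_from(c(0.2, 0.4, 0.3), c(0.25, 0.5, 0.35), roi = "left_cranial")
  )
  p$condition <- rep(c("TLV", "OLV", "OLV"), 2)
  ch <- perfusion_changes(p[sample(nrow(p)), ])  # order must not matter
  expect_equal(nrow(ch), 4)
  right <- dplyr::filter(ch, roi == "right") |> dplyr::arrange(from_timepoint)
  expect_equal(right$d_flm, c(-0.2, 0.1))
  expect_equal(right$condition, c("TLV", "OLV"))
})

test_that("perfect agreement yields the degenerate reference report", {
  set.seed(4)
  vals <- matrix(runif(15, 0.1, 0.6), 5, 3)
  vals <- vals / rowSums(vals)
  p <- tibble::tibble(
    animal = "a1",
    timepoint = rep(1:5, each = 3),
    condition = rep(c("TLV", "OLV", "OLV", "OLV", "OLV"), each = 3),
    roi = rep(c("right", "left_cranial", "left_caudal"), 5),
    pp_flm = as.vector(t(vals)),
    pp_dect = as.vector(t(vals))
  )
  ag <- method_agreement(p)
  g <- glance(ag)
  expect_equal(g$slope, 1)
  expect_equal(g$intercept, 0, tolerance = 1e-12)
  expect_equal(g$adj_r2, 1)
  expect_equal(c(g$bias, g$loa_low, g$loa_high), c(0, 0, 0))
  expect_equal(g$concordance_pct, 100)
  td <- tidy(ag)
  expect_equal(td$estimate[td$term == "slope"], 1)
})

test_that("independent noise gives chance-level concordance", {
  set.seed(33)
  ch <- tibble::tibble(d_flm = rnorm(400), d_dect = rnorm(400))
  k <- concordance(ch)
  half_width <- 100 * 2.576 * sqrt(0.25 / 400)
  expect_lt(abs(k$concordance_pct - 50), half_width)
})

test_that("the stratified report covers conditions, ROIs and the pooled stratum", {
  set.seed(6)
  vals <- matrix(runif(15, 0.1, 0.6), 5, 3)
  vals <- vals / rowSums(vals)
  p <- tibble::tibble(
    animal = "a1",
    timepoint = rep(1:5, each = 3),
    condition = rep(c("TLV", "OLV", "OLV", "OLV", "OLV"), each = 3),
    roi = rep(c("right", "left_cranial", "left_caudal"), 5),
    pp_flm = as.vector(t(vals)),
    pp_dect = as.vector(t(vals)) + rnorm(15, 0, 0.02)
  )
  rep_tab <- stratified_report(p)
  expect_equal(rep_tab$ventilated,
               c("TLV", "OLV", "all", "all", "all", "all"))
  expect_equal(rep_tab$roi, c("all", "all", "cranial", "caudal", "right", "all"))
  # condition strata partition the pairs; roi strata do too
  expect_equal(sum(rep_tab$n[1:2]), nrow(p))
  expect_equal(sum(rep_tab$n[3:5]), nrow(p))
  expect_equal(rep_tab$n[6], nrow(p))
  # the pooled row equals the unstratified battery
  g <- glance(method_agreement(p))
  expect_equal(rep_tab$slope[6], g$slope)
  expect_equal(rep_tab$bias[6], g$bias)
  expect_equal(rep_tab$concordance_pct[6], g$concordance_pct)
})

test_that("an aeration-dependent iodine bias surfaces in the right-lung stratum", {
  base <- phantom_config(noise_sd_hu = 0, weight_noise_sd = 0,
                         fluorescence_noise_sdlog = 0,
                         olv_iodine_bias = 1.3)
  rc <- vq_run_config(withr::local_tempdir(), seed = 19, phantom = base)
  res <- run_vq_study(rc)
  rep_tab <- res$report
  bias_right <- abs(rep_tab$bias[rep_tab$roi == "right"])
  bias_vent <- abs(rep_tab$bias[rep_tab$roi %in% c("cranial", "caudal")])
  expect_gt(bias_right, max(bias_vent))
  # the atelectatic lung's perfusion is overestimated by DECT
  olv <- dplyr::filter(res$pairs, condition == "OLV", roi == "right")
  expect_gt(mean(olv$pp_dect - olv$pp_flm), 0)
})
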