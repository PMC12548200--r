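# Agreement battery for paired regional perfusion measurements: ordinary
# least squares of PP_DECT on PP_FLM, Bland-Altman bias and limits of
# agreement, and change-direction (quadrant) concordance across consecutive
# timepoints, plus the stratified report (by ventilation condition and ROI).
#
# `pairs` is a tibble with columns: animal, timepoint (orderable), condition
# ("TLV"/"OLV"), roi ("right"/"left_cranial"/"left_caudal"), pp_flm, pp_dect.

check_pairs <- function(pairs) {
  need <- c("animal", "timepoint", "condition", "roi", "pp_flm", "pp_dect")
  missing <- setdiff(need, names(pairs))
  if (length(missing) > 0)
    abort(paste0("`pairs` lacks columns: ", paste(missing, collapse = ", ")))
  invisible(pairs)
}

#' Regression of one perfusion surrogate on the other
#'
#' Ordinary least squares of `pp_dect` on `pp_flm` with adjusted
#' `R^2 = 1 - (1 - R^2)(n - 1)/(n - 2)` and the slope's t-test p-value.
#'
#' @param pairs paired-measurement tibble (see package docs).
#' @return one-row tibble: `slope`, `intercept`, `adj_r2`, `p_value`, `n`.
#' @export
regress_methods <- function(pairs) {
  check_pairs(pairs)
  n <- nrow(pairs)
  if (n < 3) abort("regression needs at least 3 pairs")
  if (stats::var(pairs$pp_flm) == 0)
    abort("degenerate input: pp_flm has zero variance")
  fit <- lm(pp_dect ~ pp_flm, data = pairs)
  # summary.lm warns on exactly collinear data; perfect agreement is a
  # legitimate input here
  sm <- suppressWarnings(summary(fit))
  tss <- sum((pairs$pp_dect - mean(pairs$pp_dect))^2)
  if (tss == 0) {
    # constant response: no variance explained, slope estimates 0
    return(tibble::tibble(slope = 0, intercept = pairs$pp_dect[1],
                          adj_r2 = 0, p_value = NA_real_, n = n))
  }
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    adj_r2 = sm$adj.r.squared,
    p_value = sm$coefficients[2, 4],
    n = n
  )
}

#' Bland-Altman agreement
#'
#' Differences `d = pp_dect - pp_flm`; bias is their mean and the limits of
#' agreement are `bias +/- 1.96 * sd(d)` (sample sd, n - 1 denominator).
#'
#' @param pairs paired-measurement tibble.
#' @return one-row tibble: `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(pairs) {
  check_pairs(pairs)
  n <- nrow(pairs)
  if (n < 2) abort("Bland-Altman needs at least 2 pairs")
  d <- pairs$pp_dect - pairs$pp_flm
  bias <- mean(d)
  s <- sd(d)
  tibble::tibble(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s, n = n)
}

#' Between-timepoint changes of both methods
#'
#' For each (animal, roi) series ordered by timepoint, the change of each
#' method between consecutive timepoints. The condition of a change is that
#' of its earlier timepoint, so the switch from two-lung to one-lung
#' ventilation belongs to the TLV stratum.
#'
#' @param pairs paired-measurement tibble.
#' @return tibble with columns `animal`, `roi`, `from_timepoint`,
#'   `to_timepoint`, `condition`, `d_flm`, `d_dect`.
#' @export
perfusion_changes <- function(pairs) {
  check_pairs(pairs)
  pairs |>
    dplyr::group_by(.data$animal, .data$roi) |>
    dplyr::arrange(.data$timepoint, .by_group = TRUE) |>
    dplyr::reframe(
      from_timepoint = head(.data$timepoint, -1),
      to_timepoint = tail(.data$timepoint, -1),
      condition = head(.data$condition, -1),
      d_flm = diff(.data$pp_flm),
      d_dect = diff(.data$pp_dect)
    )
}

quadrant_of <- function(d_flm, d_dect) {
  dplyr::case_when(
    d_flm > 0 & d_dect > 0 ~ 1L,
    d_flm < 0 & d_dect > 0 ~ 2L,
    d_flm < 0 & d_dect < 0 ~ 3L,
    d_flm > 0 & d_dect < 0 ~ 4L
  )
}

#' Change-direction concordance
#'
#' Counts the quadrants of the paired changes `(d_flm, d_dect)`. The primary
#' concordance is the percentage of all non-zero change pairs falling in
#' quadrants I and III (both methods moving the same direction); the
#' literal quadrant ratio `(I + III)/(II + IV)` is reported alongside.
#' Changes that are exactly zero in either method (to within 1e-12) carry
#' no direction and are excluded and counted.
#'
#' @param changes output of [perfusion_changes()] (or a tibble with `d_flm`,
#'   `d_dect`).
#' @param zero_tol absolute change treated as a tie.
#' @return one-row tibble: `concordance_pct`, `q1`..`q4`, `n_changes`,
#'   `n_excluded`, `concordance_ratio`.
#' @export
concordance <- function(changes, zero_tol = 1e-12) {
  if (!all(c("d_flm", "d_dect") %in% names(changes)))
    abort("`changes` must carry `d_flm` and `d_dect` (see perfusion_changes)")
  tie <- abs(changes$d_flm) <= zero_tol | abs(changes$d_dect) <= zero_tol
  ch <- changes[!tie, , drop = FALSE]
  if (nrow(ch) == 0) {
    warn("no non-zero change pairs: concordance undefined")
    return(tibble::tibble(concordance_pct = NA_real_, q1 = 0L, q2 = 0L,
                          q3 = 0L, q4 = 0L, n_changes = 0L,
                          n_excluded = sum(tie),
                          concordance_ratio = NA_real_))
  }
  q <- quadrant_of(ch$d_flm, ch$d_dect)
  counts <- tabulate(q, nbins = 4)
  opp <- counts[2] + counts[4]
  tibble::tibble(
    concordance_pct = 100 * (counts[1] + counts[3]) / sum(counts),
    q1 = counts[1], q2 = counts[2], q3 = counts[3], q4 = counts[4],
    n_changes = sum(counts), n_excluded = sum(tie),
    concordance_ratio = if (opp > 0) (counts[1] + counts[3]) / opp else Inf
  )
}

#' Full agreement analysis of paired measurements
#'
#' Bundles regression, Bland-Altman and concordance into one fitted object
#' with [tidy()], [glance()] and [autoplot()] methods.
#'
#' @param pairs paired-measurement tibble.
#' @return a `vq_agreement` object.
#' @export
method_agreement <- function(pairs) {
  check_pairs(pairs)
  changes <- perfusion_changes(pairs)
  structure(list(
    pairs = pairs,
    regression = regress_methods(pairs),
    bland_altman = bland_altman(pairs),
    changes = changes,
    concordance = concordance(changes)
  ), class = "vq_agreement")
}

#' @export
print.vq_agreement <- function(x, ...) {
  r <- x$regression
  b <- x$bland_altman
  k <- x$concordance
  cat("Agreement of PP_DECT vs PP_FLM on", r$n, "paired measurements\n")
  cat(sprintf("  slope %.3f, intercept %.3f, adj R^2 %.3f (p %.3g)\n",
              r$slope, r$intercept, r$adj_r2, r$p_value))
  cat(sprintf("  bias %.4f, LoA [%.4f, %.4f]\n", b$bias, b$loa_low, b$loa_high))
  cat(sprintf("  concordance %.1f%% over %d change pairs (%d ties excluded)\n",
              k$concordance_pct, k$n_changes, k$n_excluded))
  invisible(x)
}

#' @rdname method_agreement
#' @param x a `vq_agreement` object.
#' @param ... unused.
#' @export
tidy.vq_agreement <- function(x, ...) {
  r <- x$regression
  b <- x$bland_altman
  k <- x$concordance
  tibble::tibble(
    term = c("slope", "intercept", "bias", "loa_low", "loa_high",
             "concordance_pct"),
    estimate = c(r$slope, r$intercept, b$bias, b$loa_low, b$loa_high,
                 k$concordance_pct)
  )
}

#' @rdname method_agreement
#' @export
glance.vq_agreement <- function(x, ...) {
  dplyr::bind_cols(
    x$regression,
    dplyr::select(x$bland_altman, "bias", "loa_low", "loa_high"),
    dplyr::select(x$concordance, "concordance_pct", "n_changes")
  )
}

#' Stratified agreement report
#'
#' Runs the agreement battery within each ventilation condition (all ROIs),
#' within each ROI (all conditions), and on everything, yielding one row
#' per stratum in the shape of the study's summary table. Concordance in a
#' condition stratum covers the changes starting at that condition.
#'
#' @param pairs paired-measurement tibble.
#' @return tibble with one row per stratum: `ventilated`, `roi`, `n`,
#'   `slope`, `intercept`, `adj_r2`, `p_value`, `bias`, `loa`
#'   (half-width `1.96 * sd`), `concordance_pct`.
#' @export
stratified_report <- function(pairs) {
  check_pairs(pairs)
  changes <- perfusion_changes(pairs)
  roi_strata <- c(cranial = "left_cranial", caudal = "left_caudal",
                  right = "right")
  one_row <- function(vent, roi_label, sub_pairs, sub_changes) {
    r <- regress_methods(sub_pairs)
    b <- bland_altman(sub_pairs)
    k <- concordance(sub_changes)
    tibble::tibble(ventilated = vent, roi = roi_label, n = r$n,
                   slope = r$slope, intercept = r$intercept,
                   adj_r2 = r$adj_r2, p_value = r$p_value, bias = b$bias,
                   loa = 1.96 * b$sd_diff,
                   concordance_pct = k$concordance_pct)
  }
  rows <- list()
  for (cond in c("TLV", "OLV")) {
    sub <- dplyr::filter(pairs, .data$condition == cond)
    if (nrow(sub) == 0) next
    rows[[length(rows) + 1]] <-
      one_row(cond, "all", sub, dplyr::filter(changes, .data$condition == cond))
  }
  for (lbl in names(roi_strata)) {
    sub <- dplyr::filter(pairs, .data$roi == roi_strata[[lbl]])
    if (nrow(sub) == 0) next
    rows[[length(rows) + 1]] <-
      one_row("all", lbl, sub, dplyr::filter(changes, .data$roi == roi_strata[[lbl]]))
  }
  rows[[length(rows) + 1]] <- one_row("all", "all", pairs, changes)
  dplyr::bind_rows(rows)
}
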