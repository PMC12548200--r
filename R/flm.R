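# Fluorescence-labelled microsphere processing: cube tables (12 mm
# postmortem dissection grid) -> weight-normalised fluorescence -> regional
# blood-flow fractions comparable to the DECT ROI values.

MICROSPHERE_COLUMNS <- c("cube_x_mm", "cube_y_mm", "cube_z_mm", "weight_mg",
                         "color", "fluorescence_au", "is_lung")

check_microsphere_table <- function(table) {
  missing <- setdiff(MICROSPHERE_COLUMNS, names(table))
  if (length(missing) > 0)
    abort(paste0("microsphere table lacks columns: ",
                 paste(missing, collapse = ", ")))
  invisible(table)
}

#' Read / write a microsphere cube table
#'
#' CSV schema: `cube_x_mm`, `cube_y_mm`, `cube_z_mm`, `weight_mg`, `color`,
#' `fluorescence_au`, `is_lung` (extra columns pass through).
#'
#' @param path CSV file.
#' @export
read_microsphere_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  check_microsphere_table(tab)
  tab
}

#' @rdname read_microsphere_table
#' @param table microsphere tibble.
#' @export
write_microsphere_table <- function(table, path) {
  check_microsphere_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' Weight-normalised fluorescence per cube
#'
#' For the lung cubes of one color: `value_i = fluorescence_i / x_i` with
#' cube weight `x_i`, then divided by the total so the values sum to 1.
#' Cubes with non-positive weight are rejected with a warning.
#'
#' @param table microsphere tibble.
#' @param color color label to analyse.
#' @return tibble of lung cubes with a `value` column summing to 1.
#' @export
normalize_fluorescence <- function(table, color) {
  check_microsphere_table(table)
  tab <- dplyr::filter(table, .data$color == !!color, .data$is_lung)
  if (nrow(tab) == 0) abort(paste0("color `", color, "` not present among lung cubes"))
  bad <- tab$weight_mg <= 0
  if (any(bad)) {
    warn(paste0(sum(bad), " cube(s) with non-positive weight rejected"))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (any(tab$fluorescence_au < 0)) abort("negative fluorescence")
  v <- tab$fluorescence_au / tab$weight_mg
  if (sum(v) <= 0) abort("degenerate input: all fluorescence zero")
  dplyr::mutate(tab, value = v / sum(v))
}

#' Assign cubes to regions of interest
#'
#' Each cube takes the ROI label at its centre coordinate (postmortem cubes
#' carry only their cutting-grid position, so centre-point lookup in the
#' shared phantom frame is the assignment rule); cubes whose centre falls
#' outside all ROIs are flagged `"unassigned"`.
#'
#' @param table microsphere tibble (typically from
#'   [normalize_fluorescence()]).
#' @param rois an `roi_set` from [split_rois()].
#' @param spacing voxel size of the ROI label grid, mm.
#' @return `table` with an added `roi` column.
#' @export
cubes_to_rois <- function(table, rois, spacing = c(1, 1, 1)) {
  check_microsphere_table(table)
  spacing <- check_spacing(spacing)
  dm <- dim(rois$labels)
  vi <- cbind(floor(table$cube_x_mm / spacing[1]) + 1,
              floor(table$cube_y_mm / spacing[2]) + 1,
              floor(table$cube_z_mm / spacing[3]) + 1)
  ok <- vi[, 1] >= 1 & vi[, 1] <= dm[1] & vi[, 2] >= 1 & vi[, 2] <= dm[2] &
    vi[, 3] >= 1 & vi[, 3] <= dm[3]
  lab <- rep(0L, nrow(table))
  lab[ok] <- rois$labels[vi[ok, , drop = FALSE]]
  roi <- c("unassigned", rois$roi_names)[lab + 1L]
  dplyr::mutate(table, roi = roi)
}

#' Regional microsphere blood-flow fractions
#'
#' Per-ROI sums of the weight-normalised cube values, renormalised over the
#' three ROIs (unassigned cubes are dropped and reported in the
#' `n_unassigned` attribute).
#'
#' @param labeled output of [cubes_to_rois()] carrying a `value` column.
#' @return tibble with columns `roi`, `value`, `method = "FLM"`.
#' @export
regional_flm <- function(labeled) {
  if (!"roi" %in% names(labeled) || !"value" %in% names(labeled))
    abort("`labeled` must carry `roi` and `value` columns (see cubes_to_rois)")
  roi_names <- c("right", "left_cranial", "left_caudal")
  sums <- vapply(roi_names, function(r) sum(labeled$value[labeled$roi == r]),
                 numeric(1))
  if (sum(sums) <= 0) abort("no microsphere signal inside the ROIs")
  out <- tibble::tibble(roi = roi_names, value = unname(sums) / sum(sums),
                        method = "FLM")
  attr(out, "n_unassigned") <- sum(labeled$roi == "unassigned")
  out
}
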