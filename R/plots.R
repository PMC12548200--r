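# ggplot2 graphics for the result types.

#' @rdname method_agreement
#' @param object a `vq_agreement` object.
#' @param type `"scatter"` (regression), `"bland_altman"` or
#'   `"concordance"` (change quadrants).
#' @export
autoplot.vq_agreement <- function(object,
                                  type = c("scatter", "bland_altman",
                                           "concordance"), ...) {
  type <- match.arg(type)
  if (type == "scatter") {
    r <- object$regression
    ggplot2::ggplot(object$pairs,
                    ggplot2::aes(x = .data$pp_flm, y = .data$pp_dect,
                                 colour = .data$roi)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
      ggplot2::geom_abline(slope = r$slope, intercept = r$intercept) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "PP_FLM (fraction)", y = "PP_DECT (fraction)",
                    title = sprintf("Slope %.2f, adj R² %.2f",
                                    r$slope, r$adj_r2)) +
      ggplot2::theme_minimal()
  } else if (type == "bland_altman") {
    b <- object$bland_altman
    df <- dplyr::mutate(object$pairs,
                        m = (.data$pp_dect + .data$pp_flm) / 2,
                        d = .data$pp_dect - .data$pp_flm)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d,
                                     colour = .data$roi)) +
      ggplot2::geom_hline(yintercept = c(b$bias, b$loa_low, b$loa_high),
                          linetype = c("solid", "dashed", "dashed")) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "Mean of methods", y = "PP_DECT - PP_FLM",
                    title = sprintf("Bias %.3f, LoA [%.3f, %.3f]",
                                    b$bias, b$loa_low, b$loa_high)) +
      ggplot2::theme_minimal()
  } else {
    k <- object$concordance
    ggplot2::ggplot(object$changes,
                    ggplot2::aes(x = .data$d_flm, y = .data$d_dect,
                                 colour = .data$roi)) +
      ggplot2::geom_hline(yintercept = 0) +
      ggplot2::geom_vline(xintercept = 0) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "Change of PP_FLM", y = "Change of PP_DECT",
                    title = sprintf("Concordance %.1f%%", k$concordance_pct)) +
      ggplot2::theme_minimal()
  }
}

#' Plot paired ventilation/perfusion profiles
#'
#' @param profiles output of [vq_profiles()].
#' @return a ggplot.
#' @export
plot_vq_profiles <- function(profiles) {
  long <- tidyr::pivot_longer(profiles, c("dv", "pp"), names_to = "measure",
                              values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position_mm,
                                     y = .data$fraction,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(labels = c(dv = "ventilation (dV)",
                                              pp = "perfusion (PP)")) +
    ggplot2::labs(x = paste0("Position along ", profiles$axis[1], " axis (mm)"),
                  y = "Normalised slice fraction", colour = NULL) +
    ggplot2::theme_minimal()
}
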