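#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a c(s) sedimentation-coefficient distribution
#'
#' @param object A `cs_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cs_distribution
#' @export
autoplot.cs_distribution <- function(object, ...) {
  ggplot2::ggplot(object$distribution, ggplot2::aes(x = .data$s,
                                                    y = .data$c)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "sedimentation coefficient s (S)",
      y = "c(s) (AU / S)",
      title = sprintf("c(s) distribution (rmsd %.4f AU)", object$fit_rmsd)
    ) +
    ggplot2::theme_minimal()
}

#' Plot sedimentation-velocity scans
#'
#' @param scan_set An `sv_scan_set`.
#' @param every Plot every n-th scan (default 1).
#' @return A ggplot.
#' @export
plot_sv_scans <- function(scan_set, every = 1) {
  keep <- scan_set$times[seq(1, length(scan_set$times), by = every)]
  df <- scan_set$scans[scan_set$scans$time_s %in% keep, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius_cm, y = .data$signal,
                                   colour = .data$time_s,
                                   group = .data$time_s)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_viridis_c(name = "time (s)") +
    ggplot2::labs(x = "radius (cm)", y = "signal (AU)") +
    ggplot2::theme_minimal()
}

#' Plot a sedimentation-equilibrium fit
#'
#' Data points, fitted curves and residuals per rotor speed.
#'
#' @param object An `se_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot se_fit
#' @export
autoplot.se_fit <- function(object, ...) {
  profiles <- object$profiles
  fitted <- profiles$signal - object$residuals
  df <- dplyr::mutate(tibble::as_tibble(profiles), fitted = fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius_cm)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal), size = 0.4,
                        alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::facet_wrap(~rpm, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "radius (cm)", y = "signal (AU)",
      title = sprintf("M = %.1f +/- %.1f kDa", object$molar_mass / 1000,
                      object$std_error / 1000)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a titration series with its detected onset
#'
#' @param object A `titration_series` (normalized if possible).
#' @param onset Optional `onset_result` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot titration_series
#' @export
autoplot.titration_series <- function(object, onset = NULL, ...) {
  if (!("norm_intensity" %in% names(object))) {
    object <- normalize_series(object)
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$molar_ratio,
                                            y = .data$norm_intensity)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::labs(x = "titrant : DNA molar ratio",
                  y = expression((I[i] - I[0]) / I[0])) +
    ggplot2::theme_minimal()
  if (!is.null(onset) && isTRUE(onset$detected)) {
    p <- p + ggplot2::geom_vline(xintercept = onset$onset_ratio,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}
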