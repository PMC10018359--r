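#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sedimentation-equilibrium fit
#'
#' @param x An `se_fit`.
#' @param ... Unused.
#' @return One row per fitted species with `term`, `estimate`,
#'   `std.error` and `signal_fraction`.
#' @method tidy se_fit
#' @export
tidy.se_fit <- function(x, ...) {
  masses <- c(x$molar_mass, x$molar_mass_2)
  tibble::tibble(
    term = paste0("molar_mass_", seq_along(masses)),
    estimate = masses,
    std.error = c(x$std_error, rep(NA_real_, length(masses) - 1L)),
    signal_fraction = x$fractions
  )
}

#' Glance at a sedimentation-equilibrium fit
#'
#' @param x An `se_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit-level summaries.
#' @method glance se_fit
#' @export
glance.se_fit <- function(x, ...) {
  tibble::tibble(
    chisq_reduced = x$chisq_reduced,
    rss = x$rss,
    n_obs = x$n_obs,
    n_speeds = nrow(x$baselines),
    mass_conservation = x$mass_conservation,
    unidentifiable = x$unidentifiable
  )
}

#' Tidy a c(s) distribution
#'
#' @param x A `cs_distribution`.
#' @param ... Unused.
#' @return Tibble with columns `s` (Svedberg) and `c` (AU per Svedberg).
#' @method tidy cs_distribution
#' @export
tidy.cs_distribution <- function(x, ...) x$distribution

#' Glance at a c(s) distribution
#'
#' @param x A `cs_distribution`.
#' @param ... Unused.
#' @return One-row tibble with `weight_average_s`, `total_signal`,
#'   `fit_rmsd` and `regularization_alpha`.
#' @method glance cs_distribution
#' @export
glance.cs_distribution <- function(x, ...) {
  tibble::tibble(
    weight_average_s = tryCatch(weight_average_s(x),
                                error = function(e) NA_real_),
    total_signal = sum(x$amplitudes),
    fit_rmsd = x$fit_rmsd,
    regularization_alpha = x$regularization_alpha
  )
}

#' Tidy an onset-detection result
#'
#' @param x An `onset_result`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method tidy onset_result
#' @export
tidy.onset_result <- function(x, ...) {
  tibble::tibble(
    onset_ratio = x$onset_ratio,
    pre_slope = x$pre_slope,
    post_slope = x$post_slope,
    detected = x$detected,
    fit_sse = x$fit_sse,
    f_stat = x$f_stat
  )
}
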